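# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (enumeration, brute-force search) kept
# separate from the package's code paths.

# Step-up BH adjustment written out from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest rank down
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Hypergeometric upper tail P(X >= k) by direct enumeration with choose().
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- seq(k, min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Grid-search nonlinear least squares of log(rate) = a - k * t: profile out
# the intercept (closed form given k) and refine k by iterative grid
# shrinking until the bracket is below `tol`.
oracle_grid_nls_k <- function(times, rates, k_range = c(1e-6, 1), tol = 1e-9) {
  y <- log(rates)
  sse <- function(k) {
    a <- mean(y + k * times)
    sum((y - (a - k * times))^2)
  }
  lo <- k_range[1]; hi <- k_range[2]
  while (hi - lo > tol) {
    ks <- seq(lo, hi, length.out = 41)
    errs <- vapply(ks, sse, numeric(1))
    i <- which.min(errs)
    lo <- ks[max(1, i - 1)]
    hi <- ks[min(length(ks), i + 1)]
  }
  (lo + hi) / 2
}

# Naive complete-linkage agglomeration: repeatedly merge the closest pair of
# clusters (max pairwise L1 distance between members) while that distance is
# <= max_diff.
oracle_complete_clusters <- function(membership, max_diff) {
  genes <- sort(unique(unlist(membership)))
  bin <- t(vapply(membership, function(g) as.numeric(genes %in% g),
                  numeric(length(genes))))
  d <- as.matrix(stats::dist(bin, method = "manhattan"))
  clusters <- as.list(seq_len(nrow(d)))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dd <- max(d[clusters[[i]], clusters[[j]], drop = FALSE])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    if (!is.finite(best_d) || best_d > max_diff) break
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[1]]])
    clusters[[best[1]]] <- NULL
  }
  # membership vector in input order
  out <- integer(nrow(d))
  for (ci in seq_along(clusters)) out[clusters[[ci]]] <- ci
  out
}

# Partition equality up to relabeling.
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# Brute-force consistent half-life set from a truth table.
oracle_hl_set <- function(truth, wt = "WT", kos = c("Smg5KO", "Smg6KO"),
                          conditions = c("2i", "N0-N6"),
                          min_increase = 0.10) {
  ids <- unique(truth$transcript_id)
  keep <- vapply(ids, function(id) {
    all(vapply(conditions, function(cond) {
      wt_hl <- truth$halflife[truth$transcript_id == id &
                                truth$genotype == wt &
                                truth$condition == cond]
      all(vapply(kos, function(ko) {
        ko_hl <- truth$halflife[truth$transcript_id == id &
                                  truth$genotype == ko &
                                  truth$condition == cond]
        (ko_hl - wt_hl) / wt_hl > min_increase
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  sort(ids[keep])
}
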