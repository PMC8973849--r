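#' Log2 counts-per-million with a pseudocount
#'
#' `log2((count + pc) / (library + 2 pc) * 1e6)` with per-sample library
#' sizes taken from column totals. The value is invariant to jointly scaling
#' counts and libraries.
#'
#' @param counts Wide counts tibble (first column feature ids, one column per
#'   sample) or a numeric matrix with feature rownames.
#' @param pseudocount Added to every count before the log (default 0.5); must
#'   be positive so zero counts stay finite.
#'
#' @return Log2-CPM in the same shape as the input.
#' @export
cpm_log <- function(counts, pseudocount = 0.5) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("`pseudocount` must be positive (zero counts would give -Inf).")
  }
  was_tbl <- !is.matrix(counts)
  m <- if (was_tbl) counts_to_matrix(counts) else counts
  lib <- colSums(m)
  if (any(lib <= 0)) abort("library sizes must be positive.")
  out <- log2(sweep(m + pseudocount, 2, lib + 2 * pseudocount, "/") * 1e6)
  if (was_tbl) matrix_to_tibble(out, names(counts)[1]) else out
}

#' Per-sample counts-per-million
#'
#' @inheritParams cpm_log
#' @return CPM values in the same shape as the input.
#' @export
cpm <- function(counts) {
  was_tbl <- !is.matrix(counts)
  m <- if (was_tbl) counts_to_matrix(counts) else counts
  lib <- colSums(m)
  if (any(lib <= 0)) abort("library sizes must be positive.")
  out <- sweep(m, 2, lib, "/") * 1e6
  if (was_tbl) matrix_to_tibble(out, names(counts)[1]) else out
}

# Method-of-moments empirical-Bayes squeeze of per-gene variances toward a
# scaled inverse-chi-squared prior: matching E[s^2] and Var[s^2] of the
# marginal distribution of sample variances gives the prior scale s0^2 and
# degrees of freedom d0; posterior variances are the usual weighted average.
squeeze_variances <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  if (length(s2) < 2L) return(list(d0 = 0, s0sq = mean(s2)))
  m <- mean(s2)
  v <- var(s2)
  # Var[s^2] = s0^4 * 2 * (1/df + 1/d0) under the conjugate model
  excess <- v / m^2 - 2 / df
  d0 <- if (excess <= 0) Inf else 2 / excess
  list(d0 = d0, s0sq = m)
}

#' Fold-change-threshold (TREAT-style) two-group test
#'
#' Tests, per gene, the interval null hypothesis that the absolute log2 fold
#' change is at most `tau` (default `log2(1.5)`), so that significance means
#' evidence for a biologically meaningful change, not any nonzero change.
#' The statistic uses the pooled two-sample variance with
#' `df = n_a + n_b - 2` and the p-value is
#' `P(T > (|b| - tau) / se) + P(T > (|b| + tau) / se)` for the observed
#' log2 fold change `b`. With `tau = 0` this reduces exactly to the ordinary
#' two-sided pooled t-test.
#'
#' @param a,b Numeric matrices (genes x replicates) or vectors (one gene) of
#'   log2 expression values for the reference and comparison group.
#' @param tau Fold-change-threshold on the log2 scale.
#' @param moderate If `TRUE`, per-gene variances are squeezed toward a
#'   method-of-moments inverse-chi-squared prior fitted across genes
#'   (empirical-Bayes moderation in the spirit of the moderated t); the
#'   default is the unmoderated pooled variance.
#'
#' @return Tibble with one row per gene: `log2fc` (`mean(b) - mean(a)`),
#'   `se`, `df`, `p`. Zero-variance genes get `p = 1` when `|log2fc| <= tau`
#'   and `p = 0` otherwise.
#' @examples
#' a <- matrix(rnorm(50), nrow = 10)
#' b <- matrix(rnorm(50, 1), nrow = 10)
#' treat_test(a, b, tau = log2(1.5))
#' @export
treat_test <- function(a, b, tau = log2(1.5), moderate = FALSE) {
  if (is.vector(a)) a <- matrix(a, nrow = 1)
  if (is.vector(b)) b <- matrix(b, nrow = 1)
  if (nrow(a) != nrow(b)) abort("`a` and `b` must cover the same genes.")
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) abort("need >= 2 replicates per group.")
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    abort("`tau` must be a single non-negative number.")
  }
  df <- na + nb - 2
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / df
  df_total <- df
  if (moderate) {
    pr <- squeeze_variances(s2, df)
    if (is.finite(pr$d0)) {
      s2 <- (pr$d0 * pr$s0sq + df * s2) / (pr$d0 + df)
      df_total <- df + pr$d0
    } else {
      s2 <- rep(pr$s0sq, length(s2))
      df_total <- Inf
    }
  }
  se <- sqrt(s2 * (1 / na + 1 / nb))
  beta <- mb - ma
  p <- ifelse(
    se > 0,
    pt((abs(beta) - tau) / se, df_total, lower.tail = FALSE) +
      pt((abs(beta) + tau) / se, df_total, lower.tail = FALSE),
    ifelse(abs(beta) > tau, 0, 1)
  )
  p <- pmin(p, 1)
  tibble(log2fc = beta, se = se, df = df_total, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone-enforced, capped at 1).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  check_prob(p[!is.na(p)], "p")
  p.adjust(p, method = "BH")
}

#' Classify per-gene knockout response patterns
#'
#' A gene is `"ns"` unless it is significant (`padj <= alpha`) in at least
#' one knockout; significant genes are `"up_all"` / `"down_all"` when the
#' fold-change point estimates agree in sign across all knockouts, and
#' `"mixed"` otherwise.
#'
#' @param results Long tibble with columns `gene_id`, `genotype`, `log2fc`,
#'   `padj`, one row per gene x knockout (a single timepoint).
#' @param alpha Adjusted-p cutoff (default 0.01).
#'
#' @return Tibble (`gene_id`, `pattern`).
#' @export
classify_pattern <- function(results, alpha = 0.01) {
  results <- as_tibble(results)
  stopifnot(all(c("gene_id", "genotype", "log2fc", "padj") %in% names(results)))
  results |>
    group_by(.data$gene_id) |>
    summarise(
      pattern = if (!any(.data$padj <= alpha, na.rm = TRUE)) "ns"
        else if (all(.data$log2fc > 0)) "up_all"
        else if (all(.data$log2fc < 0)) "down_all"
        else "mixed",
      .groups = "drop"
    )
}

#' Genes whose up-regulation follows the phenotype gradient
#'
#' Among genes up-regulated in all knockouts, keeps those whose fold-change
#' point estimates are strictly ordered along the knockout gradient
#' (Smg5 KO > Smg6 KO > Smg7 KO > 0 by default). Ties fail the strict
#' ordering; no significance is required for the pairwise orderings.
#'
#' @param results Long tibble (`gene_id`, `genotype`, `log2fc`) restricted to
#'   the genes to screen (typically the `up_all` genes of one timepoint).
#' @param gradient Genotype labels in decreasing expected effect order.
#'
#' @return Sorted character vector of graded gene ids.
#' @export
graded_filter <- function(results,
                          gradient = c("Smg5KO", "Smg6KO", "Smg7KO")) {
  results <- as_tibble(results)
  if (nrow(results) == 0L) return(character())
  wide <- results |>
    select("gene_id", "genotype", "log2fc") |>
    tidyr::pivot_wider(names_from = "genotype", values_from = "log2fc")
  missing_gt <- setdiff(gradient, names(wide))
  if (length(missing_gt)) {
    abort(paste0("missing genotypes: ", paste(missing_gt, collapse = ", ")))
  }
  fc <- as.matrix(wide[, gradient, drop = FALSE])
  graded <- rep(TRUE, nrow(fc))
  for (j in seq_len(length(gradient) - 1)) {
    graded <- graded & fc[, j] > fc[, j + 1]
  }
  graded <- graded & fc[, length(gradient)] > 0
  sort(wide$gene_id[which(graded)])
}

#' Graded differential expression across Smg-factor knockouts
#'
#' Full differential-expression stage: log2-CPM transform, TREAT-style
#' fold-change-threshold test of each knockout against WT within each
#' timepoint, BH adjustment per contrast, sign-pattern classification and
#' graded-gene detection.
#'
#' @param counts Wide counts tibble (first column `gene_id`, one column per
#'   sample) or matrix.
#' @param meta Sample metadata tibble with columns `sample`, `genotype`,
#'   `timepoint` matching the count columns.
#' @param wt Reference genotype label.
#' @param kos Knockout genotypes to test, in decreasing expected effect order
#'   (used as the graded gradient).
#' @param fc_null Null-hypothesis fold change: the test's null is
#'   `|FC| < fc_null` (default 1.5), i.e. `tau = log2(fc_null)`.
#' @param alpha Adjusted-p cutoff for significance (default 0.01).
#' @param pseudocount Pseudocount for the log2-CPM transform.
#' @param moderate Use empirical-Bayes variance moderation in the tests.
#'
#' @return Object of class `treat_de` with elements `results` (long tibble:
#'   `gene_id`, `timepoint`, `genotype`, `log2fc`, `se`, `df`, `p`, `padj`),
#'   `patterns` (`gene_id`, `timepoint`, `pattern`, `graded`) and
#'   `thresholds`. `tidy()` returns the results joined with patterns.
#' @export
de_analysis <- function(counts, meta, wt = "WT",
                        kos = c("Smg5KO", "Smg6KO", "Smg7KO"),
                        fc_null = 1.5, alpha = 0.01, pseudocount = 0.5,
                        moderate = FALSE) {
  meta <- as_tibble(meta)
  stopifnot(all(c("sample", "genotype", "timepoint") %in% names(meta)))
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  if (!all(meta$sample %in% colnames(m))) {
    abort("every metadata sample must be a count column.")
  }
  if (fc_null <= 0) abort("`fc_null` must be positive.")
  tau <- log2(fc_null)
  logcpm <- cpm_log(m[, meta$sample, drop = FALSE], pseudocount)

  res <- purrr::map_dfr(unique(meta$timepoint), function(tp) {
    wt_cols <- meta$sample[meta$timepoint == tp & meta$genotype == wt]
    purrr::map_dfr(kos, function(ko) {
      ko_cols <- meta$sample[meta$timepoint == tp & meta$genotype == ko]
      if (length(wt_cols) < 2L || length(ko_cols) < 2L) {
        abort(sprintf("need >= 2 replicates of %s and %s at %s.", wt, ko, tp))
      }
      tt <- treat_test(logcpm[, wt_cols, drop = FALSE],
                       logcpm[, ko_cols, drop = FALSE],
                       tau = tau, moderate = moderate)
      tibble(gene_id = rownames(logcpm), timepoint = tp, genotype = ko,
             log2fc = tt$log2fc, se = tt$se, df = tt$df, p = tt$p,
             padj = bh_adjust(tt$p))
    })
  })

  patterns <- purrr::map_dfr(unique(res$timepoint), function(tp) {
    r <- filter(res, .data$timepoint == tp)
    pat <- classify_pattern(r, alpha = alpha)
    up <- pat$gene_id[pat$pattern == "up_all"]
    graded <- graded_filter(filter(r, .data$gene_id %in% up), gradient = kos)
    mutate(pat, timepoint = tp, graded = .data$gene_id %in% graded)
  })

  out <- structure(
    list(results = res,
         patterns = select(patterns, "gene_id", "timepoint", "pattern",
                           "graded"),
         thresholds = list(fc_null = fc_null, alpha = alpha, tau = tau,
                           gradient = kos, wt = wt)),
    class = "treat_de")
  assert_de_invariants(out)
  out
}

# graded subset of up_all subset of significant, asserted on every run
assert_de_invariants <- function(de) {
  pats <- de$patterns
  if (any(pats$graded & pats$pattern != "up_all")) {
    abort("internal error: graded gene outside the up_all set.")
  }
  sig <- de$results |>
    group_by(.data$gene_id, .data$timepoint) |>
    summarise(sig = any(.data$padj <= de$thresholds$alpha, na.rm = TRUE),
              .groups = "drop")
  joined <- left_join(pats, sig, by = c("gene_id", "timepoint"))
  if (any(joined$pattern != "ns" & !joined$sig)) {
    abort("internal error: classified gene not significant in any knockout.")
  }
  invisible(de)
}

#' Graded genes of one timepoint
#'
#' @param de A `treat_de` object from [de_analysis()].
#' @param timepoint Timepoint label, e.g. `"2i"` or `"N24"`.
#' @return Sorted character vector of graded gene ids.
#' @export
graded_genes <- function(de, timepoint) {
  stopifnot(inherits(de, "treat_de"))
  sort(de$patterns$gene_id[de$patterns$timepoint == timepoint &
                             de$patterns$graded])
}

#' @export
print.treat_de <- function(x, ...) {
  cat(sprintf(
    "TREAT-style DE: %d genes, null |FC| < %g, alpha %g\n",
    length(unique(x$results$gene_id)), x$thresholds$fc_null,
    x$thresholds$alpha))
  tab <- x$patterns |>
    group_by(.data$timepoint) |>
    summarise(significant = sum(.data$pattern != "ns"),
              up_all = sum(.data$pattern == "up_all"),
              down_all = sum(.data$pattern == "down_all"),
              graded = sum(.data$graded), .groups = "drop")
  print(tab)
  invisible(x)
}

#' RIP-seq enrichment calling against input and empty-vector controls
#'
#' Defines the testable universe as transcripts with CPM at or above
#' `input_cpm` in every input sample, calls "bound" transcripts by a pooled
#' t-test (fold-change threshold 0) of IP against empty-vector IP on log2
#' CPM (BH-adjusted, positive fold change), and flags a high-confidence
#' subset with mean IP CPM at or above `high_cpm` plus an absolute log2 fold
#' change of at least `lfc_min` in the IP/input or IP/EV contrast at
#' `alpha`.
#'
#' @param counts Wide counts tibble or matrix (transcripts x samples).
#' @param meta Tibble with columns `sample`, `assay` where assay is one of
#'   `"rip_input"`, `"rip_ip"`, `"rip_ev"`.
#' @param input_cpm Universe CPM threshold on input samples (default 1).
#' @param high_cpm High-confidence mean IP CPM threshold (default 30).
#' @param alpha BH-adjusted p cutoff (default 0.05).
#' @param lfc_min Absolute log2 fold-change threshold for the
#'   high-confidence contrasts (default 1).
#' @param direction Direction required of the high-confidence contrasts:
#'   `"either"` (absolute value, default), `"up"` or `"down"`; exposed
#'   because published descriptions of such filters often leave the ratio
#'   orientation ambiguous.
#' @param pseudocount Pseudocount for log2-CPM.
#'
#' @return List of class `rip_result`: `universe` (character), `results`
#'   (per-transcript tibble with the IP/EV test and both high-confidence
#'   contrasts), `bound` and `high_confidence` (character vectors).
#' @export
rip_enrichment <- function(counts, meta, input_cpm = 1, high_cpm = 30,
                           alpha = 0.05, lfc_min = 1,
                           direction = c("either", "up", "down"),
                           pseudocount = 0.5) {
  direction <- match.arg(direction)
  meta <- as_tibble(meta)
  stopifnot(all(c("sample", "assay") %in% names(meta)))
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  m <- m[, meta$sample, drop = FALSE]
  cols <- function(a) meta$sample[meta$assay == a]
  for (a in c("rip_input", "rip_ip", "rip_ev")) {
    if (length(cols(a)) < 2L) abort(sprintf("need >= 2 %s samples.", a))
  }
  cpm_all <- cpm(m)
  universe <- rownames(m)[apply(
    cpm_all[, cols("rip_input"), drop = FALSE] >= input_cpm, 1, all)]
  empty <- structure(list(universe = character(), results = tibble(),
                          bound = character(), high_confidence = character()),
                     class = "rip_result")
  if (!length(universe)) {
    warn("empty RIP universe: no transcript passes the input CPM filter.")
    return(empty)
  }
  lc <- cpm_log(m[universe, , drop = FALSE], pseudocount)
  contrast <- function(ref_assay) {
    tt <- treat_test(lc[, cols(ref_assay), drop = FALSE],
                     lc[, cols("rip_ip"), drop = FALSE], tau = 0)
    tt$padj <- bh_adjust(tt$p)
    tt
  }
  ev <- contrast("rip_ev")
  inp <- contrast("rip_input")
  ip_cpm <- rowMeans(cpm_all[universe, cols("rip_ip"), drop = FALSE])
  dir_ok <- function(lfc) switch(direction,
    either = abs(lfc) >= lfc_min, up = lfc >= lfc_min, down = lfc <= -lfc_min)
  res <- tibble(
    transcript_id = universe,
    ip_mean_cpm = ip_cpm,
    lfc_ip_vs_ev = ev$log2fc, padj_ip_vs_ev = ev$padj,
    lfc_ip_vs_input = inp$log2fc, padj_ip_vs_input = inp$padj
  ) |>
    mutate(
      bound = .data$padj_ip_vs_ev <= alpha & .data$lfc_ip_vs_ev > 0,
      high_confidence = .data$bound & .data$ip_mean_cpm >= high_cpm &
        ((dir_ok(.data$lfc_ip_vs_input) & .data$padj_ip_vs_input <= alpha) |
           (dir_ok(.data$lfc_ip_vs_ev) & .data$padj_ip_vs_ev <= alpha))
    )
  structure(
    list(universe = universe, results = res,
         bound = sort(res$transcript_id[res$bound]),
         high_confidence = sort(res$transcript_id[res$high_confidence])),
    class = "rip_result")
}

#' @export
print.rip_result <- function(x, ...) {
  cat(sprintf("RIP enrichment: universe %d, bound %d, high-confidence %d\n",
              length(x$universe), length(x$bound),
              length(x$high_confidence)))
  invisible(x)
}
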