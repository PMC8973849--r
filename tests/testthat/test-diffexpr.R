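test_that("log2-CPM matches direct arithmetic and is scale invariant", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"),
                           s1 = c(0L, 999999L), s2 = c(10L, 100L))
  lc <- cpm_log(counts)
  expect_equal(lc$s1[1], log2(0.5 / (999999 + 1) * 1e6), tolerance = 1e-12)
  counts2 <- dplyr::mutate(counts, s1 = s1 * 2L, s2 = s2 * 2L)
  # doubling counts (and hence libraries) changes values only through the
  # pseudocount; with pseudocount scaled alongside it is exact
  lc2 <- cpm_log(counts2, pseudocount = 1)
  expect_equal(as.matrix(lc[, -1]), as.matrix(lc2[, -1]), tolerance = 1e-12)
  expect_error(cpm_log(counts, pseudocount = 0), "positive")
})

test_that("with tau = 0 the TREAT test reduces to the pooled t-test", {
  set.seed(101)
  a <- matrix(rnorm(1000 * 3), ncol = 3)
  b <- matrix(rnorm(1000 * 3, 0.3), ncol = 3)
  tt <- treat_test(a, b, tau = 0)
  pref <- vapply(seq_len(nrow(a)), function(i) {
    stats::t.test(b[i, ], a[i, ], var.equal = TRUE)$p.value
  }, numeric(1))
  expect_lt(max(abs(tt$p - pref)), 1e-12)
})

test_that("p is at least 0.5 when the estimate sits on the threshold", {
  set.seed(5)
  for (i in 1:10) {
    tau <- runif(1, 0.2, 1)
    a <- rnorm(3)
    a <- a - mean(a)         # reference mean exactly 0
    b <- rnorm(3)
    b <- b - mean(b) + tau   # force the fold change to equal tau
    tt <- treat_test(a, b, tau = tau)
    expect_gte(tt$p, 0.5)
  }
})

test_that("TREAT p is monotone in |log2fc| and in tau", {
  # common variance across genes so only |log2fc| varies
  shift <- seq(0, 2, length.out = 10)
  b <- matrix(0.1, 10, 4) + shift
  a <- matrix(rep(c(-0.1, 0.1, -0.1, 0.1), each = 10), nrow = 10)
  tt <- treat_test(a, b, tau = log2(1.5))
  expect_true(all(diff(tt$p) <= 1e-12))
  taus <- c(0, 0.3, 0.6, 1)
  ps <- vapply(taus, function(tau) treat_test(a, b, tau = tau)$p[5],
               numeric(1))
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("zero-variance groups resolve by the fold-change threshold", {
  a <- matrix(1, 2, 3)
  b <- rbind(c(1.2, 1.2, 1.2), c(3, 3, 3))
  tt <- treat_test(a, b, tau = log2(1.5))
  expect_equal(tt$p, c(1, 0))
})

test_that("moderated and unmoderated tests agree with limma", {
  set.seed(77)
  y <- matrix(rnorm(200 * 6), ncol = 6)
  design <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::lmFit(y, design)
  tr <- limma::treat(fit, lfc = log2(1.5), trend = FALSE)
  ours <- treat_test(y[, 1:3], y[, 4:6], tau = log2(1.5), moderate = TRUE)
  # the moderation priors are estimated differently (method of moments vs
  # limma's ML on log variances), so agreement is strong but not exact
  expect_gt(cor(-log10(ours$p), -log10(tr$p.value[, 2])), 0.97)
  expect_equal(ours$log2fc, unname(tr$coefficients[, 2]), tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up oracle and base cases", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(13)
  for (i in 1:5) {
    p <- runif(100)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # permutation equivariance
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
})

test_that("pattern classification follows sign agreement and significance", {
  res <- tibble::tibble(
    gene_id = rep(c("up", "mix", "ns"), each = 3),
    genotype = rep(c("Smg5KO", "Smg6KO", "Smg7KO"), 3),
    log2fc = c(1, 0.5, 0.2, 1, -0.5, 0.2, 1, 0.5, 0.2),
    padj = c(0.001, 0.5, 0.5, 0.001, 0.5, 0.5, 0.5, 0.2, 0.9))
  pat <- classify_pattern(res)
  expect_equal(pat$pattern[pat$gene_id == "up"], "up_all")
  expect_equal(pat$pattern[pat$gene_id == "mix"], "mixed")
  expect_equal(pat$pattern[pat$gene_id == "ns"], "ns")
})

test_that("graded filter demands a strictly decreasing positive gradient", {
  res <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), each = 3),
    genotype = rep(c("Smg5KO", "Smg6KO", "Smg7KO"), 3),
    log2fc = c(1.5, 1.0, 0.5,   1.0, 1.5, 0.5,   1.0, 1.0, 0.5))
  expect_equal(graded_filter(res), "g1")  # g2 wrong order, g3 tie
})

test_that("graded genes are nested within up_all within significant", {
  sim <- sim_counts(expr_sim_config(n_genes = 400, seed = 19))
  de <- de_analysis(sim$counts, sim$meta)
  td <- tidy(de)
  for (tp in unique(td$timepoint)) {
    pats <- de$patterns[de$patterns$timepoint == tp, ]
    graded <- pats$gene_id[pats$graded]
    up <- pats$gene_id[pats$pattern == "up_all"]
    sig <- pats$gene_id[pats$pattern != "ns"]
    expect_true(all(graded %in% up))
    expect_true(all(up %in% sig))
  }
})

test_that("exact-mode graded recovery matches the planted truth", {
  sim <- sim_counts(expr_sim_config(n_genes = 500, noise_mode = "exact",
                                    seed = 23))
  de <- de_analysis(sim$counts, sim$meta)
  truth_graded <- sort(sim$truth$gene_id[sim$truth$label == "graded_up"])
  expect_identical(graded_genes(de, "2i"), truth_graded)
  expect_identical(graded_genes(de, "N24"), truth_graded)
  truth_down <- sort(sim$truth$gene_id[sim$truth$label == "down_all"])
  pats <- de$patterns[de$patterns$timepoint == "2i", ]
  expect_setequal(pats$gene_id[pats$pattern == "down_all"], truth_down)
})

test_that("graded detection keeps high sensitivity and specificity with noise", {
  sim <- sim_counts(expr_sim_config(n_genes = 1500, seed = 29))
  de <- de_analysis(sim$counts, sim$meta)
  called <- graded_genes(de, "2i")
  truth <- sim$truth$gene_id[sim$truth$label == "graded_up"]
  non_truth <- sim$truth$gene_id[sim$truth$label != "graded_up"]
  sens <- mean(truth %in% called)
  spec <- mean(!non_truth %in% called)
  expect_gt(sens, 0.9)
  expect_gt(spec, 0.95)
})

test_that("RIP universe, null case and spike-in recovery behave", {
  sim <- sim_rip(rip_sim_config(n_transcripts = 300, n_enriched = 50,
                                noise_mode = "exact", seed = 31))
  rr <- rip_enrichment(sim$counts, sim$meta)
  expect_identical(rr$bound,
                   sort(sim$truth$transcript_id[sim$truth$enriched]))
  # transcript below input CPM in one sample drops from the universe
  counts <- sim$counts
  input_col <- sim$meta$sample[sim$meta$assay == "rip_input"][1]
  counts[[input_col]][1] <- 0L
  rr2 <- rip_enrichment(counts, sim$meta)
  expect_false(counts$transcript_id[1] %in% rr2$universe)
  # IP identical to EV-IP: nothing bound
  counts_null <- sim$counts
  ip_cols <- sim$meta$sample[sim$meta$assay == "rip_ip"]
  ev_cols <- sim$meta$sample[sim$meta$assay == "rip_ev"]
  for (i in seq_along(ip_cols)) {
    counts_null[[ip_cols[i]]] <- counts_null[[ev_cols[i]]]
  }
  rr3 <- rip_enrichment(counts_null, sim$meta)
  expect_length(rr3$bound, 0)
})
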