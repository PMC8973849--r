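make_catalog <- function(terms) {
  purrr::map_dfr(names(terms), function(id) {
    tibble::tibble(term_id = id, gene_id = terms[[id]])
  })
}

test_that("enrichment p equals the hypergeometric tail", {
  genes <- sprintf("g%02d", 1:20)
  study <- genes[1:5]
  # the term that covers the whole background can never be enriched
  res <- fisher_enrich(study, genes, make_catalog(list(T1 = genes)),
                       min_size = 5, max_size = 500)
  expect_equal(res$p, 1)
  # printed worked example: N=20, n=5, K=8, k=4
  cat2 <- make_catalog(list(T1 = c(genes[1:4], genes[10:13])))
  res2 <- fisher_enrich(genes[1:5], genes, cat2)
  expect_equal(res2$k, 4L)
  expect_equal(res2$p, 896 / 15504, tolerance = 1e-12)
  expect_equal(res2$p, oracle_hyper_tail(4, 8, 5, 20), tolerance = 1e-12)
})

test_that("terms outside the 5-500 size window are excluded", {
  genes <- sprintf("g%02d", 1:30)
  cat <- make_catalog(list(small = genes[1:4], ok = genes[1:5]))
  res <- fisher_enrich(genes[1:6], genes, cat)
  expect_equal(res$term_id, "ok")
  # size filter applies to the background-restricted size
  cat2 <- make_catalog(list(shrunk = c(genes[1:4], "not_in_background")))
  expect_equal(nrow(fisher_enrich(genes[1:6], genes, cat2)), 0)
  expect_equal(nrow(fisher_enrich(genes[1:6], genes, cat2,
                                  restrict_first = FALSE)), 1)
})

test_that("study outside background is an error", {
  expect_error(fisher_enrich(c("x"), c("a", "b"),
                             make_catalog(list(T1 = c("a", "b")))),
               "subset")
})

test_that("identical terms cluster together with the smaller term as representative", {
  genes <- sprintf("g%02d", 1:60)
  cat <- make_catalog(list(big = genes[1:10], twin = genes[1:10],
                           other = genes[30:50]))
  res <- fisher_enrich(genes[1:12], genes, cat)
  cl <- cluster_terms(res, max_diff = 5)
  same <- cl$cluster_id[cl$term_id %in% c("big", "twin")]
  expect_equal(same[1], same[2])
  expect_false(cl$cluster_id[cl$term_id == "other"] == same[1])
  reps <- cl$term_id[cl$is_representative & cl$term_id %in% c("big", "twin")]
  expect_equal(reps, "big")  # equal size, lexicographic tie-break
})

test_that("disjoint large terms never merge", {
  genes <- sprintf("g%03d", 1:120)
  cat <- make_catalog(list(A = genes[1:50], B = genes[51:100]))
  res <- fisher_enrich(genes[1:10], genes, cat)
  cl <- cluster_terms(res, max_diff = 5)
  expect_equal(length(unique(cl$cluster_id)), 2)
})

test_that("clustering matches a brute-force agglomeration oracle", {
  set.seed(61)
  genes <- sprintf("g%03d", 1:200)
  terms <- list()
  for (i in 1:30) {
    base <- sample(genes, sample(6:30, 1))
    terms[[sprintf("T%02d", i)]] <- base
    # seed some near-duplicates so clustering has structure
    if (i %% 3 == 0) {
      terms[[sprintf("T%02d_dup", i)]] <-
        unique(c(base[-1], sample(genes, 1)))
    }
  }
  res <- fisher_enrich(sample(genes, 30), genes, make_catalog(terms),
                       min_size = 2, max_size = 500)
  cl <- cluster_terms(res, max_diff = 5)
  oracle <- oracle_complete_clusters(attr(res, "membership")[res$term_id],
                                     max_diff = 5)
  expect_true(same_partition(cl$cluster_id, oracle))
  # each cluster's representative annotates the fewest genes
  by_cl <- split(seq_len(nrow(cl)), cl$cluster_id)
  for (idx in by_cl) {
    expect_equal(sum(cl$is_representative[idx]), 1)
    rep_K <- cl$K[idx][cl$is_representative[idx]]
    expect_true(all(rep_K <= cl$K[idx]))
  }
})

test_that("clustering is invariant to input order", {
  set.seed(62)
  genes <- sprintf("g%03d", 1:100)
  terms <- lapply(1:12, function(i) sample(genes, sample(5:20, 1)))
  names(terms) <- sprintf("T%02d", 1:12)
  res <- fisher_enrich(sample(genes, 20), genes, make_catalog(terms),
                       min_size = 2)
  cl1 <- cluster_terms(res, max_diff = 5)
  perm <- sample(nrow(res))
  res_perm <- res[perm, ]
  attr(res_perm, "membership") <- attr(res, "membership")
  cl2 <- cluster_terms(res_perm, max_diff = 5)
  j <- dplyr::left_join(
    dplyr::select(cl1, term_id, r1 = is_representative, c1 = cluster_id),
    dplyr::select(cl2, term_id, r2 = is_representative, c2 = cluster_id),
    by = "term_id")
  expect_equal(j$r1, j$r2)
  expect_true(same_partition(
    j$c1, j$c2))
})

test_that("BH runs over representatives only", {
  genes <- sprintf("g%02d", 1:40)
  cat <- make_catalog(list(A = genes[1:10], A2 = genes[1:10],
                           B = genes[20:30], C = genes[5:16]))
  out <- go_enrich(genes[1:10], genes, cat)
  expect_true(all(is.na(out$padj[!out$is_representative])))
  reps <- out[out$is_representative, ]
  expect_equal(reps$padj, bh_adjust(reps$p), tolerance = 1e-12)
  # single representative keeps its p
  single <- go_enrich(genes[1:10], genes, make_catalog(list(A = genes[1:10])))
  expect_equal(single$padj, single$p)
})

test_that("catalog files round-trip through the TSV and GMT readers", {
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(term_id = c("T1", "T1", "T2"),
                         gene_id = c("a", "b", "c")),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  cat1 <- read_term_catalog(tsv)
  expect_equal(nrow(cat1), 3)
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\ta\tb", "T2\tdesc\tc"), gmt)
  cat2 <- read_term_catalog(gmt)
  expect_setequal(cat2$gene_id[cat2$term_id == "T1"], c("a", "b"))
})
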