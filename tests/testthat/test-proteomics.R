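prot_fixture <- function(values, groups = c(A = 3, B = 3)) {
  meta <- purrr::map_dfr(names(groups), function(g) {
    tibble::tibble(group = g, replicate = seq_len(groups[[g]]))
  }) |>
    dplyr::mutate(sample = sprintf("%s_r%d", group, replicate)) |>
    dplyr::select(sample, group, replicate)
  tab <- tibble::tibble(protein_id = sprintf("p%02d", seq_len(nrow(values))),
                        is_reverse = FALSE, is_contaminant = FALSE,
                        only_modified_site = FALSE, razor_peptides = 5L)
  for (j in seq_len(ncol(values))) tab[[meta$sample[j]]] <- values[, j]
  list(table = tab, meta = meta)
}

test_that("flagged, low-razor and under-quantified groups are removed", {
  fx <- prot_fixture(matrix(rnorm(5 * 6, 25), 5))
  tab <- fx$table
  tab$is_reverse[1] <- TRUE
  tab$razor_peptides[2] <- 1L
  tab$only_modified_site[3] <- TRUE
  # protein 4: 3 values in group A, none in group B -> kept under "any"
  tab[4, fx$meta$sample[4:6]] <- NA
  # protein 5: 2 values in each group -> removed under both rules
  tab[5, fx$meta$sample[c(1, 4)]] <- NA
  tab[5, fx$meta$sample[2]] <- NA
  tab[5, fx$meta$sample[2]] <- NA
  kept_any <- filter_protein_groups(tab, fx$meta)
  expect_setequal(kept_any$protein_id, "p04")
  kept_all <- filter_protein_groups(tab, fx$meta, group_rule = "all")
  expect_length(kept_all$protein_id, 0)
})

test_that("filtering result does not depend on rule application order", {
  sim <- sim_proteomics(prot_sim_config(n_proteins = 300, seed = 11))
  a <- filter_protein_groups(sim$table, sim$meta)
  # apply the razor rule first by pre-subsetting, then the rest
  pre <- sim$table[sim$table$razor_peptides >= 2, ]
  b <- filter_protein_groups(pre, sim$meta)
  expect_identical(a, b)
})

test_that("background renormalization removes planted sample offsets", {
  set.seed(12)
  base <- matrix(rnorm(40 * 6, 25, 1), 40)
  offsets <- c(0, 2, -1, 0.5, 0, -0.25)
  shifted <- sweep(base, 2, offsets, "+")
  fx <- prot_fixture(shifted)
  bg <- fx$table$protein_id[1:15]
  out <- background_renormalize(fx$table, fx$meta, bg)
  m <- as.matrix(out[, fx$meta$sample])
  meds <- apply(m[1:15, ], 2, median)
  expect_equal(max(meds) - min(meds), 0, tolerance = 1e-12)
  # idempotent
  out2 <- background_renormalize(out, fx$meta, bg)
  expect_equal(out, out2, tolerance = 1e-12)
  # an already-balanced table is unchanged
  fx0 <- prot_fixture(base)
  out0 <- background_renormalize(fx0$table, fx0$meta, bg)
  m0 <- as.matrix(out0[, fx0$meta$sample])
  meds0 <- apply(m0[1:15, ], 2, median)
  expect_equal(max(meds0) - min(meds0), 0, tolerance = 1e-12)
  # no quantified background value in a sample is an error
  tabNA <- fx$table
  tabNA[1:15, fx$meta$sample[1]] <- NA
  expect_error(background_renormalize(tabNA, fx$meta, bg), "background")
})

test_that("imputation touches only missing cells and is seed-stable", {
  set.seed(13)
  vals <- matrix(rnorm(200 * 6, 25, 1.5), 200)
  miss <- matrix(runif(length(vals)) < 0.15, nrow(vals))
  vals[miss] <- NA
  fx <- prot_fixture(vals)
  out1 <- impute_missing(fx$table, fx$meta, seed = 99)
  out2 <- impute_missing(fx$table, fx$meta, seed = 99)
  expect_identical(out1, out2)
  m1 <- as.matrix(out1[, fx$meta$sample])
  expect_false(anyNA(m1))
  expect_equal(m1[!miss], vals[!miss])
  # a complete table passes through unchanged
  full <- prot_fixture(matrix(rnorm(30, 25), 5))
  expect_identical(impute_missing(full$table, full$meta, seed = 1),
                   full$table)
})

test_that("imputed values sit 1.8 SD below the data at 0.3 SD width", {
  set.seed(14)
  vals <- matrix(rnorm(2000 * 12, 25, 1.5), 2000)
  miss <- matrix(runif(length(vals)) < 0.2, nrow(vals))
  vals[miss] <- NA
  fx <- prot_fixture(vals, groups = c(A = 6, B = 6))
  out <- impute_missing(fx$table, fx$meta, seed = 15)
  m <- as.matrix(out[, fx$meta$sample])
  obs <- vals[!miss]
  imp <- m[miss]
  expect_lt(abs((mean(imp) - mean(obs)) / sd(obs) - (-1.8)), 0.02)
  expect_lt(abs(sd(imp) / sd(obs) - 0.3), 0.01)
})

test_that("identical groups yield no significant proteins", {
  set.seed(16)
  half <- matrix(rnorm(50 * 3, 25), 50)
  fx <- prot_fixture(cbind(half, half))
  res <- group_test(fx$table, fx$meta, c("A", "B"))
  expect_false(any(res$significant))
  expect_true(all(res$log2fc == 0))
})

test_that("strong planted interactors are fully recovered at low noise", {
  cfg <- prot_sim_config(n_proteins = 400, noise_sd = 0.1,
                         frac_missing = 0, effect_log2fc = 4,
                         frac_true_interactors = c(FL = 0.05, PTC = 0.05),
                         seed = 17)
  sim <- sim_proteomics(cfg)
  tab <- filter_protein_groups(sim$table, sim$meta)
  fl <- group_test(tab, sim$meta, c("EV", "FL"))
  ptc <- group_test(tab, sim$meta, c("EV", "PTC"))
  sets <- isoform_specific_sets(fl, ptc)
  truth <- dplyr::semi_join(sim$truth, tab, by = "protein_id")
  called_fl <- c(sets$fl_only, sets$both)
  called_ptc <- c(sets$ptc_only, sets$both)
  # every planted interactor is recovered; false calls stay at FDR scale
  expect_true(all(truth$protein_id[truth$interactor_FL] %in% called_fl))
  expect_true(all(truth$protein_id[truth$interactor_PTC] %in% called_ptc))
  expect_true(all(truth$protein_id[truth$interactor_FL &
                                     truth$interactor_PTC] %in% sets$both))
  fp <- sum(!called_fl %in% truth$protein_id[truth$interactor_FL]) +
    sum(!called_ptc %in% truth$protein_id[truth$interactor_PTC])
  expect_lte(fp, ceiling(0.05 * (length(called_fl) + length(called_ptc))))
})

test_that("isoform sets partition the union of bound sets", {
  mk <- function(ids, bound) {
    tibble::tibble(protein_id = ids, log2fc = ifelse(ids %in% bound, 2, 0),
                   se = 1, df = 6, p = 0.5,
                   padj = ifelse(ids %in% bound, 0.01, 0.9),
                   significant = ids %in% bound)
  }
  ids <- letters[1:6]
  sets <- isoform_specific_sets(mk(ids, c("a", "b", "c")),
                                mk(ids, c("b", "c", "d")))
  expect_equal(sets$both, c("b", "c"))
  expect_equal(sets$fl_only, "a")
  expect_equal(sets$ptc_only, "d")
  all_bound <- c(sets$fl_only, sets$ptc_only, sets$both)
  expect_equal(sort(all_bound), sort(unique(all_bound)))  # disjoint
  # disjoint inputs give an empty intersection
  sets2 <- isoform_specific_sets(mk(ids, c("a")), mk(ids, c("b")))
  expect_length(sets2$both, 0)
})
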