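#' Filter a protein-group table the way MaxQuant output is cleaned
#'
#' Removes reverse-database hits, contaminants, groups identified only by a
#' modified peptide, groups with fewer than `min_razor` razor peptides, and
#' groups lacking at least `min_values_per_group` quantified (non-missing)
#' values in at least one experimental group (`group_rule = "any"`; set
#' `"all"` for the strict reading that every group must reach the minimum).
#'
#' @param table Wide protein tibble: `protein_id`, logical flags
#'   `is_reverse`, `is_contaminant`, `only_modified_site`, integer
#'   `razor_peptides`, then one log2-intensity column per sample (NA =
#'   missing).
#' @param meta Tibble `sample`, `group`.
#' @param min_values_per_group Minimum quantified values required in a group.
#' @param min_razor Minimum razor peptides.
#' @param group_rule `"any"` (default) or `"all"`.
#'
#' @return The filtered table (same columns).
#' @export
filter_protein_groups <- function(table, meta, min_values_per_group = 3,
                                  min_razor = 2,
                                  group_rule = c("any", "all")) {
  group_rule <- match.arg(group_rule)
  table <- as_tibble(table)
  meta <- as_tibble(meta)
  stopifnot(all(c("sample", "group") %in% names(meta)),
            all(meta$sample %in% names(table)))
  flags <- c("is_reverse", "is_contaminant", "only_modified_site")
  for (f in flags) {
    if (is.null(table[[f]])) abort(sprintf("missing flag column `%s`.", f))
  }
  keep <- !table$is_reverse & !table$is_contaminant &
    !table$only_modified_site & table$razor_peptides >= min_razor
  m <- as.matrix(table[, meta$sample, drop = FALSE])
  counts_per_group <- vapply(split(meta$sample, meta$group), function(cols) {
    rowSums(!is.na(m[, cols, drop = FALSE]))
  }, numeric(nrow(table)))
  if (is.null(dim(counts_per_group))) {
    counts_per_group <- matrix(counts_per_group, nrow = nrow(table))
  }
  enough <- if (group_rule == "any") {
    apply(counts_per_group >= min_values_per_group, 1, any)
  } else {
    apply(counts_per_group >= min_values_per_group, 1, all)
  }
  table[keep & enough, , drop = FALSE]
}

#' Renormalize samples on the median of a background protein subset
#'
#' Corrects for unequal contaminant/background levels between samples: in
#' log2 space each sample is shifted so that its median over the designated
#' background proteins equals the grand median of those per-sample medians
#' (anchoring to the grand median preserves the overall intensity scale).
#' The operation is idempotent.
#'
#' @param table Wide protein tibble (see [filter_protein_groups()]).
#' @param meta Tibble `sample`, `group` (identifies the sample columns).
#' @param background_ids Protein ids of the background subset (as
#'   identified in control samples); must be present in the table, with at
#'   least one quantified background value per sample.
#'
#' @return The table with shifted sample columns.
#' @export
background_renormalize <- function(table, meta, background_ids) {
  table <- as_tibble(table)
  meta <- as_tibble(meta)
  if (!all(background_ids %in% table$protein_id)) {
    abort("all `background_ids` must be present in the table.")
  }
  bg_rows <- table$protein_id %in% background_ids
  meds <- vapply(meta$sample, function(s) {
    v <- table[[s]][bg_rows]
    v <- v[!is.na(v)]
    if (!length(v)) {
      abort(sprintf("sample %s has no quantified background protein.", s))
    }
    median(v)
  }, numeric(1))
  grand <- median(meds)
  for (s in meta$sample) {
    table[[s]] <- table[[s]] - meds[[s]] + grand
  }
  table
}

#' Impute missing intensities from a down-shifted normal distribution
#'
#' Missing label-free intensities are missing-not-at-random (low-abundance
#' proteins drop below the detection limit), so missing cells are replaced
#' by draws from a normal distribution modeled on the whole observed data
#' set, with mean shifted down by `shift` observed standard deviations and
#' width `width` observed standard deviations.
#'
#' @param table Wide protein tibble.
#' @param meta Tibble `sample`, `group`.
#' @param shift Down-shift of the imputation mean, in units of the
#'   whole-data SD (default -1.8).
#' @param width Width of the imputation distribution, in units of the
#'   whole-data SD (default 0.3).
#' @param seed Integer seed for the draws; the caller's RNG state is left
#'   untouched.
#'
#' @return The table with every missing intensity filled in; observed
#'   values are unchanged.
#' @export
impute_missing <- function(table, meta, shift = -1.8, width = 0.3,
                           seed = NULL) {
  if (width <= 0) abort("`width` must be positive.")
  table <- as_tibble(table)
  meta <- as_tibble(meta)
  m <- as.matrix(table[, meta$sample, drop = FALSE])
  obs <- m[!is.na(m)]
  if (length(obs) < 2L) abort("need at least two observed values to model.")
  mu <- mean(obs)
  s <- sd(obs)
  n_missing <- sum(is.na(m))
  if (n_missing == 0L) return(table)
  draws <- with_seed(seed, rnorm(n_missing, mu + shift * s, width * s))
  m[is.na(m)] <- draws
  for (j in seq_along(meta$sample)) table[[meta$sample[j]]] <- m[, j]
  table
}

#' Two-group differential abundance test at a stated FDR
#'
#' Pooled-variance t-test per protein between two sample groups (optionally
#' with empirical-Bayes variance moderation), BH-adjusted across proteins;
#' a protein is significant when `padj <= fdr`.
#'
#' @param table Wide protein tibble with no missing values in the tested
#'   samples (run [impute_missing()] first).
#' @param meta Tibble `sample`, `group`.
#' @param contrast Length-2 character `(reference, comparison)`; the
#'   reported `log2fc` is comparison minus reference.
#' @param fdr BH false-discovery-rate level (default 0.05).
#' @param moderate Use empirical-Bayes variance moderation.
#'
#' @return Tibble of class `prot_test`: `protein_id`, `log2fc`, `se`, `df`,
#'   `p`, `padj`, `significant`.
#' @export
group_test <- function(table, meta, contrast, fdr = 0.05, moderate = FALSE) {
  table <- as_tibble(table)
  meta <- as_tibble(meta)
  stopifnot(length(contrast) == 2L)
  check_prob(fdr, "fdr", open_lo = TRUE, open_hi = TRUE)
  cols_a <- meta$sample[meta$group == contrast[1]]
  cols_b <- meta$sample[meta$group == contrast[2]]
  if (length(cols_a) < 2L || length(cols_b) < 2L) {
    abort("need >= 2 samples per contrasted group.")
  }
  a <- as.matrix(table[, cols_a, drop = FALSE])
  b <- as.matrix(table[, cols_b, drop = FALSE])
  if (anyNA(a) || anyNA(b)) {
    abort("tested samples contain missing values; impute first.")
  }
  tt <- treat_test(a, b, tau = 0, moderate = moderate)
  out <- tibble(protein_id = table$protein_id, log2fc = tt$log2fc,
                se = tt$se, df = tt$df, p = tt$p,
                padj = bh_adjust(tt$p))
  out$significant <- out$padj <= fdr
  class(out) <- c("prot_test", class(out))
  attr(out, "contrast") <- contrast
  attr(out, "fdr") <- fdr
  out
}

#' Split interactors by bait isoform
#'
#' Given differential-abundance results of a full-length bait and a
#' PTC-isoform bait, each against the empty-vector control, a protein is
#' "bound" by a bait when significant with positive log2 fold change. The
#' three output sets partition `bound_FL` with `bound_PTC`'s union.
#'
#' @param fl_results,ptc_results `prot_test` tibbles over the same protein
#'   universe (full-length and PTC-isoform bait vs empty vector).
#'
#' @return List of class `isoform_sets`: sorted character vectors
#'   `fl_only`, `ptc_only`, `both`.
#' @export
isoform_specific_sets <- function(fl_results, ptc_results) {
  bound <- function(res) {
    stopifnot(all(c("protein_id", "log2fc", "significant") %in% names(res)))
    res$protein_id[res$significant & res$log2fc > 0]
  }
  if (!setequal(fl_results$protein_id, ptc_results$protein_id)) {
    abort("the two result tables must cover one protein universe.")
  }
  fl <- bound(fl_results)
  ptc <- bound(ptc_results)
  structure(list(fl_only = sort(setdiff(fl, ptc)),
                 ptc_only = sort(setdiff(ptc, fl)),
                 both = sort(intersect(fl, ptc))),
            class = "isoform_sets")
}

#' @export
print.isoform_sets <- function(x, ...) {
  cat(sprintf("Interactors: %d FL-only, %d PTC-only, %d with both isoforms\n",
              length(x$fl_only), length(x$ptc_only), length(x$both)))
  invisible(x)
}
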