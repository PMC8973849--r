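#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a SLAM-seq half-life fit
#'
#' @param x A `slam_fit` from [fit_halflives()].
#' @param ... Unused.
#' @return The estimates tibble (one row per transcript x genotype x
#'   condition).
#' @export
tidy.slam_fit <- function(x, ...) x$estimates

#' @rdname tidy.slam_fit
#' @export
glance.slam_fit <- function(x, ...) {
  ok <- x$estimates[x$estimates$status == "ok", ]
  tibble(n_fits = nrow(x$estimates), n_ok = nrow(ok),
         median_halflife = median(ok$halflife),
         cpm_threshold = x$cpm_threshold)
}

#' Tidy a graded differential-expression analysis
#'
#' @param x A `treat_de` from [de_analysis()].
#' @param ... Unused.
#' @return The long per-gene, per-knockout results joined with the pattern
#'   classification.
#' @export
tidy.treat_de <- function(x, ...) {
  left_join(x$results, x$patterns, by = c("gene_id", "timepoint"))
}

#' @rdname tidy.treat_de
#' @export
glance.treat_de <- function(x, ...) {
  x$patterns |>
    group_by(.data$timepoint) |>
    summarise(n_genes = dplyr::n(),
              significant = sum(.data$pattern != "ns"),
              up_all = sum(.data$pattern == "up_all"),
              down_all = sum(.data$pattern == "down_all"),
              graded = sum(.data$graded), .groups = "drop")
}

#' Tidy a candidate NMD target set
#'
#' @param x A `candidate_set` from [candidate_sets()].
#' @param ... Unused.
#' @return Long tibble (`set`, `gene_id`) over all six sets.
#' @export
tidy.candidate_set <- function(x, ...) {
  purrr::map_dfr(names(unclass(x)), function(nm) {
    tibble(set = nm, gene_id = x[[nm]])
  })
}

#' @rdname tidy.candidate_set
#' @export
glance.candidate_set <- function(x, ...) {
  tibble(hl_set = length(x$hl_set), graded_2i = length(x$graded_2i),
         graded_n24 = length(x$graded_n24),
         candidates_2i = length(x$candidates_2i),
         candidates_n24 = length(x$candidates_n24),
         core = length(x$core))
}

#' Tidy a RIP enrichment result
#'
#' @param x A `rip_result` from [rip_enrichment()].
#' @param ... Unused.
#' @return The per-transcript results tibble.
#' @export
tidy.rip_result <- function(x, ...) x$results

#' @rdname tidy.rip_result
#' @export
glance.rip_result <- function(x, ...) {
  tibble(universe = length(x$universe), bound = length(x$bound),
         high_confidence = length(x$high_confidence))
}

#' Tidy isoform-specific interactor sets
#'
#' @param x An `isoform_sets` from [isoform_specific_sets()].
#' @param ... Unused.
#' @return Long tibble (`set`, `protein_id`).
#' @export
tidy.isoform_sets <- function(x, ...) {
  purrr::map_dfr(names(unclass(x)), function(nm) {
    tibble(set = nm, protein_id = x[[nm]])
  })
}

#' @rdname tidy.isoform_sets
#' @export
glance.isoform_sets <- function(x, ...) {
  tibble(fl_only = length(x$fl_only), ptc_only = length(x$ptc_only),
         both = length(x$both))
}
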