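#' Combine half-life and graded-expression evidence into candidate NMD targets
#'
#' Implements the combinatorial candidate logic: a phenotypically relevant
#' NMD target must show graded up-regulation (Smg5 KO > Smg6 KO > Smg7 KO
#' vs WT) and a concomitant consistent half-life increase. Candidates per
#' timepoint are the intersection of the half-life set with the graded set
#' of that timepoint; the core set is the intersection of the two candidate
#' sets.
#'
#' @param hl_set Gene ids with a consistent half-life increase (see
#'   [consistent_hl_set()]; collapse transcripts to genes first with
#'   [genes_from_transcripts()] if needed).
#' @param graded_2i,graded_n24 Graded up-regulated gene ids in self-renewal
#'   (2i) and 24 h after 2i withdrawal (N24).
#'
#' @return Object of class `candidate_set` with sorted character sets
#'   `hl_set`, `graded_2i`, `graded_n24`, `candidates_2i`, `candidates_n24`,
#'   `core`. Set invariants (each candidate set is the stated intersection,
#'   the core is contained in every parent) are asserted on construction.
#' @examples
#' cs <- candidate_sets(c("a", "b", "c"), c("b", "c", "d"), c("c", "d"))
#' cs$core
#' @export
candidate_sets <- function(hl_set, graded_2i, graded_n24) {
  as_set <- function(x, name) {
    if (is.null(x)) x <- character()
    if (!is.character(x)) abort(sprintf("`%s` must be a character vector.", name))
    sort(unique(x))
  }
  hl_set <- as_set(hl_set, "hl_set")
  graded_2i <- as_set(graded_2i, "graded_2i")
  graded_n24 <- as_set(graded_n24, "graded_n24")
  if (length(hl_set) && (length(graded_2i) || length(graded_n24)) &&
      !length(intersect(hl_set, union(graded_2i, graded_n24)))) {
    warn(paste0("half-life and graded sets share no ids; ",
                "check that both use the same gene-id namespace."))
  }
  x <- structure(
    list(hl_set = hl_set, graded_2i = graded_2i, graded_n24 = graded_n24,
         candidates_2i = intersect(hl_set, graded_2i),
         candidates_n24 = intersect(hl_set, graded_n24),
         core = intersect(intersect(hl_set, graded_2i), graded_n24)),
    class = "candidate_set")
  stopifnot(
    setequal(x$candidates_2i, intersect(x$hl_set, x$graded_2i)),
    setequal(x$candidates_n24, intersect(x$hl_set, x$graded_n24)),
    setequal(x$core, intersect(x$candidates_2i, x$candidates_n24)),
    all(x$core %in% x$candidates_2i), all(x$core %in% x$candidates_n24),
    all(x$core %in% x$hl_set)
  )
  x
}

#' Summarise a candidate set
#'
#' @param candidates A `candidate_set` from [candidate_sets()].
#' @param file Optional path; when given, the membership table is written as
#'   TSV.
#'
#' @return Invisibly, a tibble (`set`, `gene_id`) in deterministic
#'   (lexicographic) order; a one-line count summary is printed.
#' @export
report_candidates <- function(candidates, file = NULL) {
  stopifnot(inherits(candidates, "candidate_set"))
  cat(sprintf("%d candidate genes in 2i, %d at N24, %d in both\n",
              length(candidates$candidates_2i),
              length(candidates$candidates_n24),
              length(candidates$core)))
  tab <- bind_rows(
    tibble(set = "candidates_2i", gene_id = candidates$candidates_2i),
    tibble(set = "candidates_n24", gene_id = candidates$candidates_n24),
    tibble(set = "core", gene_id = candidates$core)
  )
  if (!is.null(file)) {
    write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "Candidate NMD targets: HL set %d; graded 2i %d, N24 %d; candidates 2i %d, N24 %d; core %d\n",
    length(x$hl_set), length(x$graded_2i), length(x$graded_n24),
    length(x$candidates_2i), length(x$candidates_n24), length(x$core)))
  invisible(x)
}
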