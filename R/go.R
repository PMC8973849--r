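#' Read a term catalog from a two-column TSV or GMT file
#'
#' @param path Path to either a TSV with columns `term_id`, `gene_id` (and
#'   optionally `name`), or a GMT file (term, description, genes...).
#' @param format `"auto"` sniffs GMT by extension.
#' @return Tibble `term_id`, `gene_id`, `name`.
#' @export
read_term_catalog <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    lines <- readLines(path)
    purrr::map_dfr(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L) return(tibble())
      tibble(term_id = f[1], gene_id = f[-(1:2)], name = f[2])
    })
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("term_id", "gene_id") %in% names(tab))) {
      abort("catalog TSV needs columns term_id and gene_id.")
    }
    if (!"name" %in% names(tab)) tab$name <- tab$term_id
    as_tibble(tab[, c("term_id", "gene_id", "name")])
  }
}

normalize_catalog <- function(catalog) {
  catalog <- as_tibble(catalog)
  if (!all(c("term_id", "gene_id") %in% names(catalog))) {
    abort("catalog needs columns term_id and gene_id.")
  }
  if (!"name" %in% names(catalog)) catalog$name <- catalog$term_id
  distinct(catalog, .data$term_id, .data$gene_id, .keep_all = TRUE)
}

#' One-sided Fisher enrichment of a study set over a term catalog
#'
#' Over-representation of each catalog term in the study set against a
#' background universe (typically all expressed genes). Term gene sets are
#' restricted to the background first; by default the term-size filter
#' (5-500 annotated genes) is applied to the restricted size. The one-sided
#' enrichment p-value is the hypergeometric upper tail `P(X >= k)`.
#'
#' @param study Character vector of study gene ids; must be a subset of
#'   `background`.
#' @param background Character vector of background gene ids.
#' @param catalog Term catalog tibble (`term_id`, `gene_id`, optional
#'   `name`) or a path accepted by [read_term_catalog()].
#' @param min_size,max_size Term-size window (inclusive) applied to the
#'   background-restricted annotation count.
#' @param restrict_first Apply the size filter after restricting terms to
#'   the background (default) or to the raw annotation size.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`
#'   (via [stats::fisher.test()]).
#'
#' @return Tibble `term_id`, `name`, `k` (study hits), `K` (term size in
#'   background), `n` (study size), `N` (background size), `p`, sorted by
#'   `p`. The background-restricted membership lists are attached as the
#'   `"membership"` attribute for [cluster_terms()].
#' @export
fisher_enrich <- function(study, background, catalog,
                          min_size = 5, max_size = 500,
                          restrict_first = TRUE,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.character(catalog) && length(catalog) == 1L && file.exists(catalog)) {
    catalog <- read_term_catalog(catalog)
  }
  catalog <- normalize_catalog(catalog)
  study <- unique(study)
  background <- unique(background)
  if (!all(study %in% background)) {
    abort("`study` must be a subset of `background`.")
  }
  N <- length(background)
  n <- length(study)

  terms <- split(catalog$gene_id, catalog$term_id)
  names_map <- catalog$name[match(names(terms), catalog$term_id)]
  raw_size <- lengths(terms)
  restricted <- lapply(terms, intersect, background)
  K <- lengths(restricted)
  size_for_filter <- if (restrict_first) K else raw_size
  keep <- size_for_filter >= min_size & size_for_filter <= max_size & K > 0
  restricted <- restricted[keep]
  K <- K[keep]
  names_map <- names_map[keep]

  k <- vapply(restricted, function(g) length(intersect(g, study)), integer(1))
  p <- if (alternative == "greater") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    purrr::map2_dbl(k, K, function(ki, Ki) {
      stats::fisher.test(matrix(c(ki, Ki - ki, n - ki, N - Ki - n + ki), 2))$p.value
    })
  }
  out <- tibble(term_id = names(restricted), name = names_map,
                k = unname(k), K = unname(K), n = n, N = N,
                p = unname(p)) |>
    arrange(.data$p, .data$term_id)
  attr(out, "membership") <- restricted
  out
}

#' Cluster redundant terms and pick one representative per cluster
#'
#' Terms whose background-restricted gene sets differ by at most `max_diff`
#' genes are clustered: complete-linkage hierarchical clustering on the L1
#' (Manhattan) distance between binary gene-membership vectors, with the
#' tree cut at height `max_diff`, so all within-cluster pairwise symmetric
#' differences are at most `max_diff`. The representative of each cluster
#' is its term with the fewest annotated genes (ties broken
#' lexicographically by term id).
#'
#' @param results Output of [fisher_enrich()] (carrying the `"membership"`
#'   attribute), or any tibble with `term_id` and `K` plus an explicit
#'   `membership` argument.
#' @param max_diff Maximum number of differing genes within a cluster.
#' @param membership Optional named list term_id -> gene ids, overriding the
#'   attribute.
#'
#' @return `results` with added columns `cluster_id` (integer) and
#'   `is_representative`.
#' @export
cluster_terms <- function(results, max_diff = 5, membership = NULL) {
  membership <- membership %||% attr(results, "membership")
  if (is.null(membership)) {
    abort("no term membership available; pass `membership` or use fisher_enrich() output.")
  }
  if (nrow(results) == 0L) {
    results$cluster_id <- integer()
    results$is_representative <- logical()
    return(results)
  }
  membership <- membership[results$term_id]
  genes <- sort(unique(unlist(membership)))
  bin <- vapply(membership, function(g) as.numeric(genes %in% g),
                numeric(length(genes)))
  bin <- t(bin)  # terms x genes
  rownames(bin) <- results$term_id
  if (nrow(bin) == 1L) {
    cl <- setNames(1L, results$term_id)
  } else {
    d <- stats::dist(bin, method = "manhattan")
    hc <- stats::hclust(d, method = "complete")
    cl <- stats::cutree(hc, h = max_diff)
  }
  results$cluster_id <- unname(cl[results$term_id])
  rep_ids <- results |>
    group_by(.data$cluster_id) |>
    summarise(rep = .data$term_id[order(.data$K, .data$term_id)][1],
              .groups = "drop")
  results$is_representative <- results$term_id %in% rep_ids$rep
  attr(results, "membership") <- membership
  results
}

#' BH adjustment over cluster-representative terms only
#'
#' @param results Output of [cluster_terms()].
#' @return `results` with a `padj` column; non-representative terms carry
#'   `NA` (they are reported through their representative).
#' @export
adjust_representatives <- function(results) {
  if (is.null(results$is_representative)) {
    abort("run cluster_terms() first.")
  }
  results$padj <- NA_real_
  idx <- which(results$is_representative)
  results$padj[idx] <- bh_adjust(results$p[idx])
  results
}

#' GO-style over-representation with term clustering
#'
#' Convenience wrapper running [fisher_enrich()], [cluster_terms()] and
#' [adjust_representatives()] in sequence.
#'
#' @inheritParams fisher_enrich
#' @inheritParams cluster_terms
#' @return A tibble of class `go_enrichment` (enrichment columns plus
#'   `cluster_id`, `is_representative`, `padj`).
#' @export
go_enrich <- function(study, background, catalog, min_size = 5,
                      max_size = 500, max_diff = 5,
                      alternative = c("greater", "two.sided")) {
  res <- fisher_enrich(study, background, catalog, min_size = min_size,
                       max_size = max_size, alternative = alternative)
  res <- adjust_representatives(cluster_terms(res, max_diff = max_diff))
  class(res) <- c("go_enrichment", class(res))
  res
}
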