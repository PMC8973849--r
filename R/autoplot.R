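#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_violin geom_hline
#'   geom_vline geom_col facet_wrap labs theme_bw scale_y_log10
#' @export
ggplot2::autoplot

#' Plot half-life distributions per genotype and condition
#'
#' @param object A `slam_fit` from [fit_halflives()].
#' @param ... Unused.
#' @return A ggplot: violin plots of half-lives (minutes, log scale) of the
#'   `status == "ok"` fits, faceted by condition.
#' @export
autoplot.slam_fit <- function(object, ...) {
  est <- filter(object$estimates, .data$status == "ok")
  ggplot(est, aes(x = .data$genotype, y = .data$halflife)) +
    geom_violin(fill = "grey85") +
    scale_y_log10() +
    facet_wrap(~condition) +
    labs(x = NULL, y = "mRNA half-life (min)") +
    theme_bw()
}

#' Fold-change pattern plot of a graded DE analysis
#'
#' @param object A `treat_de` from [de_analysis()].
#' @param timepoint Optional single timepoint to show (default: all).
#' @param ... Unused.
#' @return A ggplot: per-knockout log2 fold changes of significant genes,
#'   graded genes highlighted.
#' @export
autoplot.treat_de <- function(object, timepoint = NULL, ...) {
  dat <- tidy(object)
  if (!is.null(timepoint)) {
    tp <- timepoint
    dat <- filter(dat, .data$timepoint == tp)
  }
  dat <- filter(dat, .data$pattern != "ns")
  ggplot(dat, aes(x = .data$genotype, y = .data$log2fc,
                  colour = .data$graded, group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.25) +
    geom_hline(yintercept = 0, linetype = 2) +
    facet_wrap(~timepoint) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    labs(x = NULL, y = "log2 fold change vs WT", colour = "graded") +
    theme_bw()
}

#' Dot plot of representative enriched terms
#'
#' @param object A `go_enrichment` from [go_enrich()].
#' @param max_terms Show at most this many representatives (by adjusted p).
#' @param ... Unused.
#' @return A ggplot of representative terms: hits vs -log10 adjusted p.
#' @export
autoplot.go_enrichment <- function(object, max_terms = 20, ...) {
  reps <- filter(as_tibble(object), .data$is_representative) |>
    arrange(.data$padj) |>
    head(max_terms)
  reps$name <- factor(reps$name, levels = rev(reps$name))
  ggplot(reps, aes(x = -log10(.data$padj), y = .data$name,
                   size = .data$k)) +
    geom_point(colour = "steelblue") +
    labs(x = expression(-log[10] ~ adjusted ~ p), y = NULL,
         size = "study hits") +
    theme_bw()
}

#' Volcano plot of a protein-group differential test
#'
#' @param object A `prot_test` from [group_test()].
#' @param ... Unused.
#' @return A ggplot: log2 fold change vs -log10 p, significant proteins
#'   highlighted.
#' @export
autoplot.prot_test <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot(dat, aes(x = .data$log2fc, y = -log10(pmax(.data$p, 1e-300)),
                  colour = .data$significant)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    labs(x = "log2 fold change", y = expression(-log[10] ~ p),
         colour = sprintf("padj <= %g", attr(object, "fdr") %||% 0.05)) +
    theme_bw()
}

#' Conservation identity distribution with a focal region marked
#'
#' @param identities Output of [region_identity()].
#' @param focal_region_id Optional `region_id` to mark.
#' @return A ggplot: identity distributions per region class.
#' @export
plot_identity_distribution <- function(identities, focal_region_id = NULL) {
  identities <- as_tibble(identities)
  p <- ggplot(identities, aes(x = .data$region_class, y = .data$identity)) +
    geom_violin(fill = "grey85") +
    labs(x = NULL, y = "percent identity") +
    theme_bw()
  if (!is.null(focal_region_id)) {
    focal <- filter(identities, .data$region_id == focal_region_id)
    p <- p + geom_hline(yintercept = focal$identity, colour = "deeppink3",
                        linetype = 2)
  }
  p
}
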