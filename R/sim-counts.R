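#' Configuration for the RNA-seq count simulator
#'
#' Emulates a four-genotype (WT plus three Smg-factor knockouts), two
#' timepoint bulk RNA-seq design with negative-binomial counts and a planted
#' subset of genes whose up-regulation follows the knockout gradient
#' (Smg5 KO > Smg6 KO > Smg7 KO), mirroring the graded differentiation
#' phenotype, plus a planted subset down-regulated equally in all knockouts.
#'
#' @param n_genes Number of genes.
#' @param genotypes Genotype labels; the first is the reference (WT).
#' @param timepoints Timepoint labels.
#' @param n_replicates Replicates per genotype x timepoint.
#' @param library_size Expected reads per sample; per-sample expected counts
#'   are renormalized to sum to it.
#' @param dispersion Negative-binomial dispersion (Var = mu + dispersion *
#'   mu^2); must be positive in `"nb"` mode.
#' @param frac_graded_up Fraction of genes planted as graded up-regulated.
#' @param graded_log2fc Named log2 fold changes vs WT for the graded genes,
#'   strictly decreasing and positive along the knockout gradient.
#' @param frac_down_all Fraction of genes planted as down-regulated equally
#'   in all knockouts.
#' @param down_log2fc Log2 fold change (negative) of the down-regulated
#'   class in every knockout.
#' @param noise_mode `"nb"` draws negative-binomial counts; `"exact"` emits
#'   rounded expected means (the dispersion-to-zero limit), so recovery can
#'   be tested by equality.
#' @param seed Integer seed.
#'
#' @return An `expr_sim_config` list.
#' @seealso [sim_counts()]
#' @export
expr_sim_config <- function(n_genes = 2000,
                            genotypes = c("WT", "Smg5KO", "Smg6KO", "Smg7KO"),
                            timepoints = c("2i", "N24"),
                            n_replicates = 4,
                            library_size = 2e6,
                            dispersion = 0.02,
                            frac_graded_up = 0.05,
                            graded_log2fc = c(Smg5KO = 2, Smg6KO = 1.5,
                                              Smg7KO = 1),
                            frac_down_all = 0.05,
                            down_log2fc = -1.5,
                            noise_mode = c("nb", "exact"),
                            seed = NULL) {
  noise_mode <- match.arg(noise_mode)
  check_count(n_genes, "n_genes")
  check_count(n_replicates, "n_replicates", min = 2)
  check_prob(frac_graded_up, "frac_graded_up")
  check_prob(frac_down_all, "frac_down_all")
  if (frac_graded_up + frac_down_all > 1) {
    abort("planted fractions must sum to at most 1.")
  }
  if (noise_mode == "nb" && (!is.finite(dispersion) || dispersion <= 0)) {
    abort("`dispersion` must be positive in nb mode.")
  }
  kos <- setdiff(genotypes, genotypes[1])
  if (!all(kos %in% names(graded_log2fc))) {
    abort("`graded_log2fc` must name every knockout genotype.")
  }
  g <- graded_log2fc[kos]
  if (any(g <= 0) || is.unsorted(rev(g), strictly = TRUE)) {
    abort("`graded_log2fc` must be strictly decreasing and positive along the gradient.")
  }
  if (down_log2fc >= 0) abort("`down_log2fc` must be negative.")
  structure(
    list(n_genes = as.integer(n_genes), genotypes = genotypes,
         timepoints = timepoints, n_replicates = as.integer(n_replicates),
         library_size = library_size, dispersion = dispersion,
         frac_graded_up = frac_graded_up, graded_log2fc = g,
         frac_down_all = frac_down_all, down_log2fc = down_log2fc,
         noise_mode = noise_mode, seed = seed),
    class = "expr_sim_config"
  )
}

#' Simulate a gene x sample count matrix with planted graded genes
#'
#' @param config An [expr_sim_config()].
#'
#' @return A list of class `expr_sim`:
#' \describe{
#'   \item{counts}{Wide tibble, `gene_id` plus one column per sample.}
#'   \item{meta}{Tibble `sample`, `genotype`, `timepoint`, `replicate`.}
#'   \item{truth}{Tibble `gene_id`, `label` (`graded_up`, `down_all`,
#'     `null`) and the planted per-knockout log2 fold changes.}
#' }
#' @examples
#' sim <- sim_counts(expr_sim_config(n_genes = 50, seed = 1))
#' sim$truth
#' @export
sim_counts <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    ids <- sprintf("gene%05d", seq_len(ng))
    wt <- config$genotypes[1]
    kos <- setdiff(config$genotypes, wt)

    labels <- rep("null", ng)
    n_up <- round(config$frac_graded_up * ng)
    n_down <- round(config$frac_down_all * ng)
    planted <- if (n_up + n_down > 0) sample.int(ng, n_up + n_down) else integer()
    labels[planted[seq_len(n_up)]] <- "graded_up"
    if (n_down > 0) labels[planted[n_up + seq_len(n_down)]] <- "down_all"

    # per-gene baseline relative abundance (gamma-distributed, heavy-ish
    # tail), floored so every gene is comfortably expressed
    w <- stats::rgamma(ng, shape = 0.7, rate = 1)
    w <- pmax(w, 0.05)

    lfc <- matrix(0, ng, length(kos), dimnames = list(ids, kos))
    for (ko in kos) {
      lfc[labels == "graded_up", ko] <- config$graded_log2fc[[ko]]
      lfc[labels == "down_all", ko] <- config$down_log2fc
    }

    meta <- tidyr::expand_grid(
      genotype = config$genotypes,
      timepoint = config$timepoints,
      replicate = seq_len(config$n_replicates)
    ) |>
      mutate(sample = sprintf("%s_%s_r%d", .data$genotype, .data$timepoint,
                              .data$replicate)) |>
      select("sample", "genotype", "timepoint", "replicate")

    counts <- matrix(0, ng, nrow(meta), dimnames = list(ids, meta$sample))
    for (i in seq_len(nrow(meta))) {
      gt <- meta$genotype[i]
      mu <- w * if (gt == wt) 1 else 2^lfc[, gt]
      mu <- mu / sum(mu) * config$library_size
      counts[, i] <- if (config$noise_mode == "exact") round(mu)
        else rnbinom(ng, mu = mu, size = 1 / config$dispersion)
    }

    truth <- tibble(gene_id = ids, label = labels)
    for (ko in kos) truth[[paste0("log2fc_", ko)]] <- lfc[, ko]

    structure(
      list(counts = matrix_to_tibble(counts, "gene_id"), meta = meta,
           truth = truth, config = config),
      class = "expr_sim")
  })
}

#' @export
print.expr_sim <- function(x, ...) {
  cat(sprintf(
    "RNA-seq simulation: %d genes x %d samples (%s noise); planted: %s\n",
    nrow(x$truth), nrow(x$meta), x$config$noise_mode,
    paste(sprintf("%s=%d", names(table(x$truth$label)),
                  as.integer(table(x$truth$label))), collapse = ", ")))
  invisible(x)
}

#' Configuration for the RIP-seq triplet simulator
#'
#' Emulates matched input / IP / empty-vector-IP count libraries with a
#' planted set of transcripts enriched in the IP. Libraries are not
#' renormalized after planting so that unenriched transcripts have exactly
#' equal expected counts in IP and empty-vector IP.
#'
#' @param n_transcripts Number of transcripts.
#' @param n_enriched Number of planted bound transcripts.
#' @param enrich_log2fc Log2 enrichment of bound transcripts in the IP over
#'   both controls.
#' @param n_replicates Replicates per assay.
#' @param library_size Expected reads of the input library.
#' @param dispersion NB dispersion (`"nb"` mode).
#' @param noise_mode `"nb"` or `"exact"`.
#' @param seed Integer seed.
#'
#' @return A `rip_sim_config` list.
#' @export
rip_sim_config <- function(n_transcripts = 1000, n_enriched = 50,
                           enrich_log2fc = 3, n_replicates = 3,
                           library_size = 2e6, dispersion = 0.05,
                           noise_mode = c("nb", "exact"), seed = NULL) {
  noise_mode <- match.arg(noise_mode)
  check_count(n_transcripts, "n_transcripts")
  check_count(n_enriched, "n_enriched")
  if (n_enriched > n_transcripts) abort("`n_enriched` exceeds `n_transcripts`.")
  if (enrich_log2fc <= 0) abort("`enrich_log2fc` must be positive.")
  if (noise_mode == "nb" && dispersion <= 0) abort("`dispersion` must be positive.")
  structure(
    list(n_transcripts = as.integer(n_transcripts),
         n_enriched = as.integer(n_enriched),
         enrich_log2fc = enrich_log2fc,
         n_replicates = as.integer(n_replicates),
         library_size = library_size, dispersion = dispersion,
         noise_mode = noise_mode, seed = seed),
    class = "rip_sim_config")
}

#' Simulate RIP-seq input / IP / empty-vector count triplets
#'
#' @param config A [rip_sim_config()].
#' @return List of class `rip_sim` with `counts` (wide tibble), `meta`
#'   (`sample`, `assay`, `replicate`) and `truth` (`transcript_id`,
#'   `enriched`).
#' @export
sim_rip <- function(config) {
  stopifnot(inherits(config, "rip_sim_config"))
  with_seed(config$seed, {
    nt <- config$n_transcripts
    ids <- sprintf("tx%05d", seq_len(nt))
    enriched <- ids %in% sample(ids, config$n_enriched)

    w <- stats::rgamma(nt, shape = 0.7, rate = 1)
    w <- pmax(w, 0.05)
    mu_base <- w / sum(w) * config$library_size

    meta <- tidyr::expand_grid(
      assay = c("rip_input", "rip_ip", "rip_ev"),
      replicate = seq_len(config$n_replicates)
    ) |>
      mutate(sample = sprintf("%s_r%d", .data$assay, .data$replicate)) |>
      select("sample", "assay", "replicate")

    counts <- matrix(0, nt, nrow(meta), dimnames = list(ids, meta$sample))
    for (i in seq_len(nrow(meta))) {
      mu <- mu_base
      if (meta$assay[i] == "rip_ip") {
        mu[enriched] <- mu[enriched] * 2^config$enrich_log2fc
      }
      counts[, i] <- if (config$noise_mode == "exact") round(mu)
        else rnbinom(nt, mu = mu, size = 1 / config$dispersion)
    }

    structure(
      list(counts = matrix_to_tibble(counts, "transcript_id"), meta = meta,
           truth = tibble(transcript_id = ids, enriched = enriched),
           config = config),
      class = "rip_sim")
  })
}
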