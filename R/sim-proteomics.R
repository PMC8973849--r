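#' Configuration for the label-free proteomics simulator
#'
#' Emulates a MaxQuant-style protein-group table from a pulldown experiment
#' with an empty-vector control group and one or more bait groups: normal
#' log2 intensities, planted interactors enriched in their bait group,
#' missing values (completely at random or intensity-dependent),
#' and reverse/contaminant/modified-only/low-razor flags.
#'
#' @param n_proteins Number of protein groups.
#' @param groups Named integer vector: replicates per group, e.g.
#'   `c(EV = 4, FL = 4, PTC = 4)`. The first group is the control.
#' @param intensity_mean,intensity_sd Mean and between-protein SD of log2
#'   intensities.
#' @param noise_sd Within-protein replicate SD (log2 units).
#' @param frac_missing Overall fraction of missing cells.
#' @param missing_mode `"mcar"` (completely at random) or
#'   `"intensity_dependent"` (lower-intensity cells more likely missing,
#'   calibrated to the same overall fraction).
#' @param frac_true_interactors Named fractions of proteins planted as true
#'   interactors per bait group (independently drawn per bait, so overlaps
#'   arise naturally).
#' @param effect_log2fc Log2 enrichment of a true interactor in its bait
#'   group.
#' @param flags_frac Named fractions `reverse`, `contaminant`,
#'   `only_modified`, `low_razor` of flagged entries.
#' @param seed Integer seed.
#'
#' @return A `prot_sim_config` list.
#' @seealso [sim_proteomics()]
#' @export
prot_sim_config <- function(n_proteins = 2000,
                            groups = c(EV = 4, FL = 4, PTC = 4),
                            intensity_mean = 25, intensity_sd = 1.5,
                            noise_sd = 0.3,
                            frac_missing = 0.2,
                            missing_mode = c("intensity_dependent", "mcar"),
                            frac_true_interactors = c(FL = 0.04, PTC = 0.04),
                            effect_log2fc = 4,
                            flags_frac = c(reverse = 0.01, contaminant = 0.01,
                                           only_modified = 0.005,
                                           low_razor = 0.01),
                            seed = NULL) {
  missing_mode <- match.arg(missing_mode)
  check_count(n_proteins, "n_proteins")
  if (is.null(names(groups)) || any(groups < 2)) {
    abort("`groups` must be named with >= 2 replicates each.")
  }
  if (intensity_sd <= 0 || noise_sd <= 0) abort("SDs must be positive.")
  check_prob(frac_missing, "frac_missing")
  check_prob(frac_true_interactors, "frac_true_interactors")
  baits <- names(frac_true_interactors)
  if (!all(baits %in% names(groups)[-1])) {
    abort("`frac_true_interactors` must name non-control groups.")
  }
  check_prob(flags_frac, "flags_frac")
  structure(
    list(n_proteins = as.integer(n_proteins), groups = groups,
         intensity_mean = intensity_mean, intensity_sd = intensity_sd,
         noise_sd = noise_sd, frac_missing = frac_missing,
         missing_mode = missing_mode,
         frac_true_interactors = frac_true_interactors,
         effect_log2fc = effect_log2fc, flags_frac = flags_frac,
         seed = seed),
    class = "prot_sim_config")
}

#' Simulate a protein-group intensity table with known interactors
#'
#' @param config A [prot_sim_config()].
#'
#' @return List of class `prot_sim`:
#' \describe{
#'   \item{table}{Wide tibble: `protein_id`, flags, `razor_peptides`, one
#'     log2-intensity column per sample (NA = missing).}
#'   \item{meta}{Tibble `sample`, `group`, `replicate`.}
#'   \item{truth}{Tibble `protein_id` plus one logical `interactor_<bait>`
#'     column per bait group.}
#' }
#' @export
sim_proteomics <- function(config) {
  stopifnot(inherits(config, "prot_sim_config"))
  with_seed(config$seed, {
    np <- config$n_proteins
    ids <- sprintf("prot%05d", seq_len(np))
    baits <- names(config$frac_true_interactors)

    meta <- purrr::map_dfr(names(config$groups), function(g) {
      tibble(group = g, replicate = seq_len(config$groups[[g]]))
    }) |>
      mutate(sample = sprintf("%s_r%d", .data$group, .data$replicate)) |>
      select("sample", "group", "replicate")

    base <- rnorm(np, config$intensity_mean, config$intensity_sd)
    interactor <- matrix(FALSE, np, length(baits),
                         dimnames = list(ids, baits))
    for (b in baits) {
      interactor[, b] <- runif(np) < config$frac_true_interactors[[b]]
    }

    m <- matrix(NA_real_, np, nrow(meta), dimnames = list(ids, meta$sample))
    for (i in seq_len(nrow(meta))) {
      mu <- base
      g <- meta$group[i]
      if (g %in% baits) {
        mu[interactor[, g]] <- mu[interactor[, g]] + config$effect_log2fc
      }
      m[, i] <- rnorm(np, mu, config$noise_sd)
    }

    if (config$frac_missing > 0) {
      n_cells <- length(m)
      if (config$missing_mode == "mcar") {
        miss <- runif(n_cells) < config$frac_missing
      } else {
        # missingness decreasing linearly in the intensity rank, with the
        # configured overall fraction in expectation
        r <- rank(m, ties.method = "average") / (n_cells + 1)
        pmiss <- pmin(1, pmax(0, 2 * config$frac_missing * (1 - r)))
        miss <- runif(n_cells) < pmiss
      }
      m[miss] <- NA_real_
    }

    ff <- config$flags_frac
    flag <- function(fr) runif(np) < fr
    is_reverse <- flag(ff[["reverse"]])
    is_contaminant <- flag(ff[["contaminant"]])
    only_modified <- flag(ff[["only_modified"]])
    low_razor <- flag(ff[["low_razor"]])
    razor <- ifelse(low_razor, 1L, 2L + rpois(np, 5))

    table <- tibble(protein_id = ids, is_reverse = is_reverse,
                    is_contaminant = is_contaminant,
                    only_modified_site = only_modified,
                    razor_peptides = as.integer(razor))
    for (j in seq_len(ncol(m))) table[[colnames(m)[j]]] <- m[, j]

    truth <- tibble(protein_id = ids)
    for (b in baits) truth[[paste0("interactor_", b)]] <- interactor[, b]

    structure(list(table = table, meta = meta, truth = truth,
                   config = config),
              class = "prot_sim")
  })
}
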