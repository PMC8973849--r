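#' Configuration for the SLAM-seq conversion-count simulator
#'
#' Describes a metabolic-labeling experiment: transcripts are labeled with
#' 4-thiouridine (4SU), chemically converted so labeled uridines read as T>C
#' mismatches, and chased with uridine so the conversion rate of each
#' transcript decays exponentially at its own degradation rate. Time zero is
#' the end of the 4SU labeling window; all times are minutes.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param halflife_range Length-2 numeric, minutes; per-transcript baseline
#'   half-lives are drawn uniformly from this interval.
#' @param chase_times Uridine-chase sampling times in minutes, sorted
#'   ascending and starting at 0.
#' @param labeling_rate Probability that a T position in a 4SU-labeled
#'   transcript reads as C at chase time 0.
#' @param background_rate Probability of a spurious T>C call in unlabeled
#'   RNA (sequencing error plus SNPs); must be below `labeling_rate`. May be
#'   0 for idealized data.
#' @param t_coverage Expected number of sequenced T positions per transcript
#'   per sample.
#' @param genotypes Named numeric vector of multiplicative half-life effects,
#'   e.g. `c(WT = 1, Smg5KO = 1.3, Smg6KO = 1.3)`; the effect multiplies the
#'   baseline half-life of affected transcripts in that genotype.
#' @param frac_affected Fraction of transcripts that actually carry the
#'   genotype half-life effect; the rest decay at the WT rate in every
#'   genotype (NMD regulates a subset of the transcriptome, not all of it).
#' @param conditions Condition labels; baseline half-lives are drawn
#'   independently per condition.
#' @param reads_per_transcript Expected reads per transcript per sample, used
#'   for CPM filtering downstream.
#' @param noise_mode `"binomial"` draws coverages (Poisson), conversions
#'   (binomial) and reads (Poisson); `"exact"` uses rounded expectations so
#'   downstream recovery can be tested by equality.
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return A `slam_sim_config` list.
#' @seealso [sim_slam()]
#' @export
slam_sim_config <- function(n_transcripts = 500,
                            halflife_range = c(30, 600),
                            chase_times = c(0, 180, 360),
                            labeling_rate = 0.08,
                            background_rate = 0.001,
                            t_coverage = 5000,
                            genotypes = c(WT = 1, Smg5KO = 1.3, Smg6KO = 1.3),
                            frac_affected = 0.4,
                            conditions = c("2i", "N0-N6"),
                            reads_per_transcript = 100,
                            noise_mode = c("binomial", "exact"),
                            seed = NULL) {
  noise_mode <- match.arg(noise_mode)
  check_count(n_transcripts, "n_transcripts")
  if (length(halflife_range) != 2L || any(!is.finite(halflife_range)) ||
      any(halflife_range <= 0) || halflife_range[1] > halflife_range[2]) {
    abort("`halflife_range` must be positive minutes (low, high).")
  }
  if (length(chase_times) < 2L || chase_times[1] != 0 ||
      is.unsorted(chase_times, strictly = TRUE) || any(chase_times < 0)) {
    abort("`chase_times` must be sorted ascending starting at 0.")
  }
  check_prob(labeling_rate, "labeling_rate", open_lo = TRUE, open_hi = TRUE)
  check_prob(background_rate, "background_rate", open_hi = TRUE)
  if (background_rate >= labeling_rate) {
    abort("`background_rate` must be below `labeling_rate`.")
  }
  check_prob(frac_affected, "frac_affected")
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes))) ||
      any(!is.finite(genotypes)) || any(genotypes <= 0)) {
    abort("`genotypes` must be a named vector of positive half-life multipliers.")
  }
  structure(
    list(n_transcripts = as.integer(n_transcripts),
         halflife_range = as.numeric(halflife_range),
         chase_times = as.numeric(chase_times),
         labeling_rate = labeling_rate,
         background_rate = background_rate,
         t_coverage = t_coverage,
         genotypes = genotypes,
         frac_affected = frac_affected,
         conditions = conditions,
         reads_per_transcript = reads_per_transcript,
         noise_mode = noise_mode,
         seed = seed),
    class = "slam_sim_config"
  )
}

#' Simulate SLAM-seq T>C conversion-count tables with known half-lives
#'
#' Forward model of a 4SU pulse / uridine chase: at chase time t the expected
#' conversion rate of a transcript with half-life HL is
#' `background + (labeling - background) * 2^(-t / HL)`. A matched no-4SU
#' sample carries conversions at the background rate only. Half-lives are
#' drawn per transcript and condition; knockout genotypes multiply the
#' half-life of the affected transcript subset.
#'
#' @param config A [slam_sim_config()].
#'
#' @return A list of class `slam_sim`:
#' \describe{
#'   \item{conversions}{Tibble with one row per transcript x genotype x
#'     condition x sample: `transcript_id`, `genotype`, `condition`,
#'     `chase_time`, `is_4su`, `t_coverage`, `tc_count`, `read_count`.}
#'   \item{truth}{Tibble of the half-life used per transcript x genotype x
#'     condition, with the `affected` flag.}
#' }
#' @examples
#' sim <- sim_slam(slam_sim_config(n_transcripts = 5, seed = 1))
#' head(sim$conversions)
#' @export
sim_slam <- function(config) {
  stopifnot(inherits(config, "slam_sim_config"))
  empty_conv <- tibble(
    transcript_id = character(), genotype = character(),
    condition = character(), chase_time = numeric(), is_4su = logical(),
    t_coverage = integer(), tc_count = integer(), read_count = integer()
  )
  empty_truth <- tibble(
    transcript_id = character(), genotype = character(),
    condition = character(), halflife = numeric(), affected = logical()
  )
  if (config$n_transcripts == 0L) {
    return(structure(list(conversions = empty_conv, truth = empty_truth,
                          config = config), class = "slam_sim"))
  }

  with_seed(config$seed, {
    ids <- sprintf("tx%04d", seq_len(config$n_transcripts))
    n_aff <- round(config$frac_affected * config$n_transcripts)
    affected <- ids %in% sample(ids, n_aff)

    truth <- tidyr::expand_grid(
      transcript_id = ids,
      condition = config$conditions
    )
    truth$base_hl <- runif(nrow(truth), config$halflife_range[1],
                           config$halflife_range[2])
    truth <- tidyr::expand_grid(
      truth,
      genotype = names(config$genotypes)
    )
    truth$affected <- affected[match(truth$transcript_id, ids)]
    truth$halflife <- truth$base_hl *
      ifelse(truth$affected, config$genotypes[truth$genotype], 1)
    truth <- truth[, c("transcript_id", "genotype", "condition",
                       "halflife", "affected")]

    grid <- tidyr::expand_grid(
      truth,
      chase_time = config$chase_times
    )
    grid$is_4su <- TRUE
    bg <- truth
    bg$chase_time <- 0
    bg$is_4su <- FALSE
    grid <- bind_rows(grid, bg)

    lr <- config$labeling_rate
    br <- config$background_rate
    grid$rate <- ifelse(
      grid$is_4su,
      br + (lr - br) * 2^(-grid$chase_time / grid$halflife),
      br
    )
    n <- nrow(grid)
    if (config$noise_mode == "exact") {
      grid$t_coverage <- as.integer(round(config$t_coverage))
      grid$tc_count <- as.integer(round(grid$t_coverage * grid$rate))
      grid$read_count <- as.integer(round(config$reads_per_transcript))
    } else {
      grid$t_coverage <- rpois(n, config$t_coverage)
      grid$tc_count <- rbinom(n, grid$t_coverage, grid$rate)
      grid$read_count <- rpois(n, config$reads_per_transcript)
    }

    conversions <- grid[, c("transcript_id", "genotype", "condition",
                            "chase_time", "is_4su", "t_coverage",
                            "tc_count", "read_count")]
    conversions <- arrange(conversions, .data$transcript_id, .data$genotype,
                           .data$condition, dplyr::desc(.data$is_4su),
                           .data$chase_time)
    truth <- arrange(truth, .data$transcript_id, .data$genotype,
                     .data$condition)
    structure(list(conversions = conversions, truth = truth, config = config),
              class = "slam_sim")
  })
}

#' @export
print.slam_sim <- function(x, ...) {
  cat(sprintf(
    "SLAM-seq simulation: %d transcripts, %d genotypes, %d conditions (%s noise)\n",
    x$config$n_transcripts, length(x$config$genotypes),
    length(x$config$conditions), x$config$noise_mode))
  print(head(x$conversions))
  invisible(x)
}
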