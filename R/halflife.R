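#' T>C conversion rate of a transcript in one sample
#'
#' @param t_coverage Number of sequenced T positions (vectorized).
#' @param tc_count Number of T>C conversions observed at those positions.
#'
#' @return Numeric vector `tc_count / t_coverage`; `NA` where coverage is 0
#'   (the transcript is unusable in that sample).
#' @export
conversion_rate <- function(t_coverage, tc_count) {
  if (any(tc_count > t_coverage, na.rm = TRUE)) {
    abort("`tc_count` cannot exceed `t_coverage`.")
  }
  if (any(t_coverage < 0 | tc_count < 0, na.rm = TRUE)) {
    abort("counts must be non-negative.")
  }
  ifelse(t_coverage >= 1, tc_count / t_coverage, NA_real_)
}

#' Subtract the no-4SU background from a conversion rate
#'
#' Rates at or below background become `NA` rather than being clamped to a
#' small positive value: a clamped rate would enter the log-linear fit as an
#' arbitrarily low point and bias the slope, so the timepoint is treated as
#' unusable instead.
#'
#' @param rate Raw conversion rate(s) in `[0, 1]`.
#' @param background Background conversion rate(s) in `[0, 1]`.
#'
#' @return `rate - background` where positive, `NA` otherwise.
#' @export
subtract_background <- function(rate, background) {
  check_prob(rate[!is.na(rate)], "rate")
  check_prob(background[!is.na(background)], "background")
  adj <- rate - background
  ifelse(!is.na(adj) & adj > 0, adj, NA_real_)
}

#' Transcripts passing a CPM filter in every sample of a condition
#'
#' Mirrors the half-life pipeline's expression filter: a transcript is
#' retained for fitting only if it reaches `threshold` counts per million in
#' every sample of the genotype x condition being fit. The library size is
#' the per-sample total of assigned reads in the conversion table.
#'
#' @param conversions Conversion-count tibble (see [sim_slam()]); samples are
#'   distinguished by `chase_time` and `is_4su` within a genotype x condition.
#' @param threshold CPM threshold (default 2).
#'
#' @return Tibble of (`transcript_id`, `genotype`, `condition`) combinations
#'   that pass.
#' @export
filter_cpm <- function(conversions, threshold = 2) {
  conversions <- as_tibble(conversions)
  conversions |>
    group_by(.data$genotype, .data$condition, .data$chase_time,
             .data$is_4su) |>
    mutate(cpm = .data$read_count * 1e6 / sum(.data$read_count)) |>
    group_by(.data$transcript_id, .data$genotype, .data$condition) |>
    summarise(pass = all(.data$cpm >= threshold), .groups = "drop") |>
    filter(.data$pass) |>
    select(-"pass")
}

#' Fit a single-exponential decay to conversion rates at chase times
#'
#' Ordinary least squares of `ln(rate)` on time with a free intercept; the
#' decay constant is minus the slope and the half-life is `ln(2) / k`. At
#' least three finite positive background-subtracted rates are required.
#'
#' @param chase_times Chase times in minutes.
#' @param rates Background-subtracted conversion rates (NA = unusable point).
#'
#' @return One-row tibble: `k` (per minute), `halflife` (minutes),
#'   `n_points`, `r_squared`, `status`. `status` is `"ok"`,
#'   `"nonpositive_rate"` (fewer than 3 usable points) or `"nonpositive_k"`
#'   (non-decaying signal); `halflife` is `NA` unless `status == "ok"`.
#' @examples
#' fit_halflife(c(0, 180, 360), c(0.08, 0.04, 0.02)) # half-life 180 min
#' @export
fit_halflife <- function(chase_times, rates) {
  stopifnot(length(chase_times) == length(rates))
  usable <- is.finite(rates) & rates > 0
  failed <- function(status) {
    tibble(k = NA_real_, halflife = NA_real_,
           n_points = sum(usable), r_squared = NA_real_, status = status)
  }
  if (sum(usable) < 3L) return(failed("nonpositive_rate"))
  t <- chase_times[usable]
  y <- log(rates[usable])
  tc <- t - mean(t)
  slope <- sum(tc * y) / sum(tc^2)
  k <- -slope
  fitted <- mean(y) + slope * tc
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum((y - fitted)^2) / sst else NA_real_
  if (!is.finite(k) || k <= 0) {
    out <- failed("nonpositive_k")
    out$k <- k
    out$r_squared <- r2
    return(out)
  }
  tibble(k = k, halflife = log(2) / k, n_points = sum(usable),
         r_squared = r2, status = "ok")
}

#' Estimate mRNA half-lives for every transcript, genotype and condition
#'
#' Runs the whole SLAM-seq estimation pipeline on a conversion-count table:
#' CPM filtering, conversion-rate calculation, no-4SU background
#' subtraction, and per-transcript single-exponential fitting within each
#' genotype x condition.
#'
#' @param conversions Conversion-count tibble with columns `transcript_id`,
#'   `genotype`, `condition`, `chase_time`, `is_4su`, `t_coverage`,
#'   `tc_count`, `read_count` (see [sim_slam()]). Each transcript needs one
#'   `is_4su = FALSE` record per genotype x condition carrying the
#'   background.
#' @param cpm_threshold Minimum CPM in every sample of the fitted condition;
#'   transcripts below it are reported with status `"low_cpm"`.
#'
#' @return An object of class `slam_fit`; `tidy()` returns the estimates
#'   tibble (`transcript_id`, `genotype`, `condition`, `k`, `halflife`,
#'   `n_points`, `r_squared`, `status`).
#' @export
fit_halflives <- function(conversions, cpm_threshold = 2) {
  conversions <- as_tibble(conversions)
  required <- c("transcript_id", "genotype", "condition", "chase_time",
                "is_4su", "t_coverage", "tc_count", "read_count")
  missing_cols <- setdiff(required, names(conversions))
  if (length(missing_cols)) {
    abort(paste0("conversion table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  keep <- filter_cpm(conversions, threshold = cpm_threshold)
  keep$.pass <- TRUE

  dat <- conversions |>
    mutate(rate = conversion_rate(.data$t_coverage, .data$tc_count)) |>
    left_join(keep, by = c("transcript_id", "genotype", "condition")) |>
    mutate(.pass = !is.na(.data$.pass))

  est <- dat |>
    group_by(.data$transcript_id, .data$genotype, .data$condition) |>
    summarise(
      fit = {
        bg_rate <- .data$rate[!.data$is_4su]
        bg <- if (length(bg_rate)) mean(bg_rate) else 0
        tt <- .data$chase_time[.data$is_4su]
        rr <- subtract_background(.data$rate[.data$is_4su], bg)
        if (!all(.data$.pass)) {
          list(tibble(k = NA_real_, halflife = NA_real_,
                      n_points = NA_integer_, r_squared = NA_real_,
                      status = "low_cpm"))
        } else {
          list(fit_halflife(tt, rr))
        }
      },
      .groups = "drop"
    ) |>
    tidyr::unnest("fit")

  structure(list(estimates = est, cpm_threshold = cpm_threshold),
            class = "slam_fit")
}

#' @export
print.slam_fit <- function(x, ...) {
  n_ok <- sum(x$estimates$status == "ok")
  cat(sprintf("SLAM-seq half-life fit: %d estimates, %d ok (CPM >= %g)\n",
              nrow(x$estimates), n_ok, x$cpm_threshold))
  print(head(x$estimates))
  invisible(x)
}

#' Does a knockout increase the half-life by more than a threshold?
#'
#' @param wt_halflife,ko_halflife Half-lives in minutes (vectorized); both
#'   must come from `status == "ok"` fits.
#' @param min_increase Minimum relative increase; the comparison is strict,
#'   so exactly `+10\%` does not qualify at the default.
#'
#' @return Logical vector: `(ko - wt) / wt > min_increase`.
#' @export
hl_increase <- function(wt_halflife, ko_halflife, min_increase = 0.10) {
  if (any(wt_halflife <= 0 | ko_halflife <= 0, na.rm = TRUE)) {
    abort("half-lives must be positive.")
  }
  (ko_halflife - wt_halflife) / wt_halflife > min_increase
}

#' Transcripts with a consistent half-life increase across comparisons
#'
#' Selects transcripts whose half-life increases by more than `min_increase`
#' in every knockout-vs-WT comparison in every condition (by default Smg5
#' and Smg6 knockouts in both self-renewal and early differentiation: four
#' direct comparisons), requiring an `"ok"` fit on both sides of each
#' comparison.
#'
#' @param estimates Estimates tibble from [fit_halflives()] (or `tidy()` of a
#'   `slam_fit`), or the `slam_fit` itself.
#' @param wt Genotype label of the reference.
#' @param kos Knockout genotype labels to compare against `wt`.
#' @param conditions Condition labels entering the comparisons.
#' @param min_increase Strict relative half-life increase threshold.
#'
#' @return Sorted character vector of transcript ids.
#' @export
consistent_hl_set <- function(estimates, wt = "WT",
                              kos = c("Smg5KO", "Smg6KO"),
                              conditions = c("2i", "N0-N6"),
                              min_increase = 0.10) {
  if (inherits(estimates, "slam_fit")) estimates <- estimates$estimates
  estimates <- as_tibble(estimates)
  est <- filter(estimates, .data$condition %in% conditions,
                .data$genotype %in% c(wt, kos))
  wt_est <- filter(est, .data$genotype == wt) |>
    select("transcript_id", "condition", wt_halflife = "halflife",
           wt_status = "status")
  ko_est <- filter(est, .data$genotype != wt) |>
    select("transcript_id", "condition", "genotype", ko_halflife = "halflife",
           ko_status = "status")
  cmp <- left_join(ko_est, wt_est, by = c("transcript_id", "condition"))
  n_needed <- length(kos) * length(conditions)
  cmp |>
    group_by(.data$transcript_id) |>
    summarise(
      ok = dplyr::n() == n_needed &&
        all(.data$ko_status == "ok") && all(.data$wt_status == "ok") &&
        all(hl_increase(.data$wt_halflife, .data$ko_halflife, min_increase)),
      .groups = "drop"
    ) |>
    filter(.data$ok) |>
    pull("transcript_id") |>
    unname() |>
    sort()
}

#' Collapse a transcript-level half-life set to gene level
#'
#' A gene qualifies when any of its transcripts qualifies.
#'
#' @param transcript_set Character vector of transcript ids.
#' @param tx2gene Tibble with columns `transcript_id`, `gene_id`.
#'
#' @return Sorted character vector of gene ids.
#' @export
genes_from_transcripts <- function(transcript_set, tx2gene) {
  tx2gene <- as_tibble(tx2gene)
  stopifnot(all(c("transcript_id", "gene_id") %in% names(tx2gene)))
  sort(unique(tx2gene$gene_id[tx2gene$transcript_id %in% transcript_set]))
}
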