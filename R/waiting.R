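#' Waiting time to cART initiation under deferred treatment
#'
#' Under the deferred strategy (Scenario B) a patient is measured at entry
#' (t = 0) with their baseline CD4 count and re-measured every 6 months while
#' CD4 falls by a fixed amount per period. Treatment starts at the first
#' measurement *strictly below* the threshold; a measurement exactly at the
#' threshold keeps waiting. A patient at or above the threshold at entry
#' therefore waits at least one period, so the minimum wait is 6 months.
#'
#' @param baseline_cd4 CD4 count at entry, cells/uL (vectorised).
#' @param decline_per_period CD4 decline per 6-month period, cells/uL
#'   (`> 0`).
#' @param threshold Initiation threshold, cells/uL (`> 0`; default 250).
#' @param period_years Length of one measurement period in years (0.5).
#' @return A tibble with one row per input: `baseline_cd4`,
#'   `periods_waited`, `wait_years`, `cd4_at_initiation` (floored at 0).
#'
#' @examples
#' wait_to_initiation(265)  # one period; starts at 219.25 cells/uL
#' wait_to_initiation(345)  # 345 -> 299.25 -> 253.5 -> 207.75: three periods
#' @export
wait_to_initiation <- function(baseline_cd4, decline_per_period = 45.75,
                               threshold = 250, period_years = 0.5) {
  if (any(decline_per_period <= 0)) {
    stop("decline_per_period must be > 0", call. = FALSE)
  }
  if (any(threshold <= 0)) stop("threshold must be > 0", call. = FALSE)
  k <- ifelse(baseline_cd4 < threshold, 0,
              floor((baseline_cd4 - threshold) / decline_per_period) + 1)
  tibble::tibble(
    baseline_cd4 = baseline_cd4,
    periods_waited = as.integer(k),
    wait_years = k * period_years,
    cd4_at_initiation = pmax(baseline_cd4 - k * decline_per_period, 0)
  )
}

#' Pre-treatment CD4 trajectory at measurement points
#'
#' The sequence of biannual CD4 measurements for one waiting patient, from
#' entry through the initiating measurement.
#'
#' @inheritParams wait_to_initiation
#' @param baseline_cd4 A single CD4 count.
#' @return A tibble with columns `time` (years) and `cd4` (cells/uL, floored
#'   at 0).
#' @export
cd4_trajectory <- function(baseline_cd4, decline_per_period = 45.75,
                           threshold = 250, period_years = 0.5) {
  stopifnot(length(baseline_cd4) == 1)
  w <- wait_to_initiation(baseline_cd4, decline_per_period, threshold, period_years)
  k <- w$periods_waited
  tibble::tibble(
    time = (0:k) * period_years,
    cd4 = pmax(baseline_cd4 - (0:k) * decline_per_period, 0)
  )
}

#' CD4 decline rate at a named percentile
#'
#' The model evaluates the deferred arm at the 25th, 50th and 75th
#' percentiles of the published between-patient distribution of 6-month CD4
#' decline.
#'
#' @param decline The `$decline` component of a `cea_parameters` object.
#' @param which One of `"q25"`, `"median"`, `"q75"`.
#' @return The decline in cells/uL per 6-month period.
#' @export
decline_at_percentile <- function(decline, which = c("median", "q25", "q75")) {
  which <- match.arg(which)
  switch(which,
    q25 = decline$q25_per_period,
    median = decline$median_per_period,
    q75 = decline$q75_per_period
  )
}

#' On-treatment CD4 trajectory (first-year immune reconstitution)
#'
#' After cART initiation CD4 recovers linearly at the first-year
#' reconstitution rate and is held constant thereafter; only the resulting
#' stratum (at or below 350 vs above 350 cells/uL) feeds the hospitalization
#' model.
#'
#' @param cd4_start CD4 at initiation, cells/uL.
#' @param t_since_initiation Years since initiation (vectorised, `>= 0`).
#' @param reconstitution_rate First-year recovery rate, cells/uL per year.
#' @return CD4 count at `t_since_initiation`.
#' @export
on_treatment_cd4 <- function(cd4_start, t_since_initiation,
                             reconstitution_rate = 114) {
  if (any(t_since_initiation < 0)) {
    stop("t_since_initiation must be non-negative", call. = FALSE)
  }
  cd4_start + reconstitution_rate * pmin(t_since_initiation, 1)
}

#' Waiting summary for the ten-bin cohort
#'
#' Applies the waiting rule to every baseline CD4 bin midpoint and
#' summarises: per-bin waits and initiation CD4 counts, the wait range in
#' months, and order statistics of the initiation CD4 (for ten bins the
#' median is the mean of the 5th and 6th order statistics).
#'
#' @param params A `cea_parameters` object.
#' @param decline Decline percentile, see [decline_at_percentile()].
#' @return A list with `table` (per-bin tibble), `wait_range_months`,
#'   `median_start_cd4`, and `start_cd4_quartiles`.
#'
#' @examples
#' s <- cohort_wait_summary()
#' s$wait_range_months   # 6 to 18
#' round(s$median_start_cd4)  # 226
#' @export
cohort_wait_summary <- function(params = cea_parameters(),
                                decline = c("median", "q25", "q75")) {
  decline <- match.arg(decline)
  d <- decline_at_percentile(params$decline, decline)
  bins <- cd4_bins(params)
  w <- wait_to_initiation(bins$midpoint, d, params$cd4_threshold,
                          params$measurement_interval)
  tab <- dplyr::bind_cols(bins, dplyr::select(w, -"baseline_cd4")) |>
    dplyr::mutate(wait_months = .data$wait_years * 12)
  list(
    table = tab,
    wait_range_months = range(tab$wait_months),
    median_start_cd4 = stats::median(tab$cd4_at_initiation),
    start_cd4_quartiles = stats::quantile(tab$cd4_at_initiation, c(0.25, 0.75))
  )
}
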