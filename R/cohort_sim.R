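#' Fit a lognormal between-patient CD4 decline distribution
#'
#' The published decline data give only three quantiles (median and
#' quartiles of the 6-month CD4 decline). A lognormal is anchored at the
#' median (`meanlog = log(median)`) with the log-scale spread taken from the
#' quartile ratio, `sdlog = log(q75/q25) / (2 * qnorm(0.75))`. The fitted
#' median and the fitted interquartile *ratio* then match the inputs
#' exactly; the individual fitted quartiles match only approximately because
#' the published quartiles are not log-symmetric about the median (their
#' geometric mean is 43.7, not 45.75).
#'
#' @param median,q25,q75 Quantiles of the 6-month decline, cells/uL
#'   (`0 < q25 < median < q75`).
#' @return An object of class `decline_distribution`: a list with `meanlog`,
#'   `sdlog`, and `fitted_quartiles`.
#'
#' @examples
#' fit <- fit_decline_distribution()
#' qlnorm(0.5, fit$meanlog, fit$sdlog) # 45.75
#' @export
fit_decline_distribution <- function(median = 45.75, q25 = 30.65, q75 = 62.35) {
  if (!(0 < q25 && q25 < median && median < q75)) {
    stop("quantiles must satisfy 0 < q25 < median < q75", call. = FALSE)
  }
  sdlog <- (log(q75) - log(q25)) / (2 * qnorm(0.75))
  structure(
    list(
      meanlog = log(median),
      sdlog = sdlog,
      fitted_quartiles = qlnorm(c(0.25, 0.5, 0.75), log(median), sdlog)
    ),
    class = "decline_distribution"
  )
}

#' Sample a synthetic patient cohort
#'
#' Generates individual patients with the statistical structure the
#' deterministic cohort model assumes: baseline CD4 uniform over the
#' eligibility window (250-350 cells/uL), and a patient-specific 6-month
#' CD4 decline drawn from the fitted lognormal (or from a three-point
#' q25/median/q75 distribution with weights 1/4, 1/2, 1/4 — the only three
#' rates the deterministic model ever evaluates). A `bin_midpoints` baseline
#' mode draws from the ten bin-midpoint atoms instead of the continuum, for
#' exact-equivalence checks against the bin model.
#'
#' @param n_patients Number of patients (`>= 1`).
#' @param params A `cea_parameters` object.
#' @param seed Integer seed; required, so every cohort is reproducible.
#' @param decline_distribution `"lognormal"` or `"three_point"`.
#' @param baseline `"uniform"` (continuous over the CD4 window) or
#'   `"bin_midpoints"`.
#' @return A tibble with columns `id`, `baseline_cd4`, `decline_per_period`.
#'
#' @examples
#' sample_cohort(5, seed = 1)
#' @export
sample_cohort <- function(n_patients, params = cea_parameters(), seed,
                          decline_distribution = c("lognormal", "three_point"),
                          baseline = c("uniform", "bin_midpoints")) {
  decline_distribution <- match.arg(decline_distribution)
  baseline <- match.arg(baseline)
  stopifnot(n_patients >= 1)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  set.seed(seed)
  cd4 <- switch(baseline,
    uniform = runif(n_patients, params$cd4_range[1], params$cd4_range[2]),
    bin_midpoints = sample(cd4_bins(params)$midpoint, n_patients, replace = TRUE)
  )
  d <- params$decline
  dec <- switch(decline_distribution,
    lognormal = {
      fit <- fit_decline_distribution(d$median_per_period, d$q25_per_period,
                                      d$q75_per_period)
      rlnorm(n_patients, fit$meanlog, fit$sdlog)
    },
    three_point = sample(
      c(d$q25_per_period, d$median_per_period, d$q75_per_period),
      n_patients, replace = TRUE, prob = c(0.25, 0.5, 0.25)
    )
  )
  tibble::tibble(id = seq_len(n_patients), baseline_cd4 = cd4,
                 decline_per_period = dec)
}

#' Microsimulate a patient cohort through both scenarios
#'
#' Applies the identical deterministic pipeline ([evaluate_patients()]) to
#' every patient and summarises: cohort means and Monte-Carlo standard
#' errors of DALYs averted, incremental cost, YLL, YLD and waiting time, and
#' the cohort ICER as a ratio of means (with a delta-method standard
#' error). With a degenerate cohort (bin-midpoint baselines, fixed median
#' decline) the cohort means equal the deterministic mean row exactly, which
#' is the module's core validation.
#'
#' @param cohort A cohort tibble from [sample_cohort()] (or any data frame
#'   with `baseline_cd4` and `decline_per_period`).
#' @param params A `cea_parameters` object.
#' @return An object of class `cea_microsim`: a list with `patients` (the
#'   per-patient outcome tibble), `summary` (tibble of mean/se per
#'   quantity), `icer`, `icer_se`, and `n`. Has [tidy()] and [glance()]
#'   methods.
#' @export
microsimulate <- function(cohort, params = cea_parameters()) {
  if (nrow(cohort) == 0) stop("cohort must be nonempty", call. = FALSE)
  pts <- evaluate_patients(cohort, params)
  n <- nrow(pts)
  vars <- c(daly_averted = "daly_averted", incremental_cost = "incremental_cost",
            yll = "yll", yld = "yld", wait_years = "b_wait_years")
  summ <- purrr::imap(vars, function(col, nm) {
    x <- pts[[col]]
    tibble::tibble(quantity = nm, mean = mean(x),
                   se = if (n > 1) sd(x) / sqrt(n) else NA_real_)
  }) |>
    purrr::list_rbind()
  mx <- mean(pts$incremental_cost)
  my <- mean(pts$daly_averted)
  ratio <- mx / my
  icer_se <- if (n > 1) {
    vx <- stats::var(pts$incremental_cost)
    vy <- stats::var(pts$daly_averted)
    cxy <- stats::cov(pts$incremental_cost, pts$daly_averted)
    sqrt((vx + ratio^2 * vy - 2 * ratio * cxy) / n) / abs(my)
  } else {
    NA_real_
  }
  structure(
    list(patients = pts, summary = summ, icer = ratio, icer_se = icer_se, n = n),
    class = "cea_microsim"
  )
}

#' @export
print.cea_microsim <- function(x, ...) {
  cat(sprintf("Microsimulation of %d patients\n", x$n))
  print(x$summary)
  cat(sprintf("ICER (ratio of means): $%.1f per DALY averted (MC se %.1f)\n",
              x$icer, x$icer_se))
  invisible(x)
}

#' @rdname microsimulate
#' @param x,object A `cea_microsim` object.
#' @param ... Unused.
#' @method tidy cea_microsim
#' @export
tidy.cea_microsim <- function(x, ...) {
  x$summary
}

#' @rdname microsimulate
#' @method glance cea_microsim
#' @export
glance.cea_microsim <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n = x$n,
    daly_averted = s$mean[s$quantity == "daly_averted"],
    daly_averted_se = s$se[s$quantity == "daly_averted"],
    incremental_cost = s$mean[s$quantity == "incremental_cost"],
    incremental_cost_se = s$se[s$quantity == "incremental_cost"],
    icer = x$icer,
    icer_se = x$icer_se
  )
}
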