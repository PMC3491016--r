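#' Annual inpatient days for a CD4 stratum and treatment status
#'
#' Total expected inpatient days per year (admissions with a severe
#' opportunistic infection plus admissions without one) for a patient in a
#' given CD4 stratum, on or off cART.
#'
#' @param stratum `"cd4_201_350"` or `"cd4_gt_350"`.
#' @param on_cart Logical; is the patient on treatment?
#' @param params A `cea_parameters` object (only `$inpatient` is used).
#' @return Days per year.
#'
#' @examples
#' inpatient_days_per_year("cd4_201_350", on_cart = FALSE) # 10.8 + 3.0
#' @export
inpatient_days_per_year <- function(stratum, on_cart,
                                    params = cea_parameters()) {
  r <- params$inpatient$rates
  if (!all(stratum %in% unique(r$stratum))) {
    stop("unknown CD4 stratum: ", paste(setdiff(stratum, r$stratum), collapse = ", "),
         call. = FALSE)
  }
  tots <- inpatient_day_totals(params)
  key <- paste(stratum, on_cart)
  unname(tots[key])
}

# named vector of with-OI + without-OI day totals per (stratum, on_cart) cell
inpatient_day_totals <- function(params) {
  r <- params$inpatient$rates
  agg <- dplyr::summarise(
    dplyr::group_by(r, .data$stratum, .data$on_cart),
    days = sum(.data$days_per_year), .groups = "drop"
  )
  stats::setNames(agg$days, paste(agg$stratum, agg$on_cart))
}

#' Discounted lifetime treatment and monitoring cost
#'
#' The pre-treatment monitoring stream (annual waiting cost over the waiting
#' interval, discounted from model entry) plus the on-treatment stream (the
#' annual cART drug + monitoring total times the discounted life-years lived
#' on treatment).
#'
#' @param wait_years Waiting time before initiation, years (a multiple of
#'   the 6-month measurement interval; 0 for immediate initiation).
#' @param post_start_life_years Undiscounted life-years lived on treatment.
#' @param params A `cea_parameters` object.
#' @return A tibble with `waiting_monitoring`, `cart_and_monitoring`, and
#'   their sum `treatment_total` (USD).
#' @export
lifetime_treatment_cost <- function(wait_years, post_start_life_years,
                                    params = cea_parameters()) {
  if (any(wait_years < 0) || any(post_start_life_years < 0)) {
    stop("wait_years and post_start_life_years must be non-negative", call. = FALSE)
  }
  rate <- params$discount$annual_rate
  conv <- params$discount$convention
  waiting <- params$costs$waiting_total_annual *
    discount_years(wait_years, 0, rate, conv)
  on_cart <- params$costs$treatment_total_annual *
    discount_years(post_start_life_years, wait_years, rate, conv)
  tibble::tibble(
    waiting_monitoring = waiting,
    cart_and_monitoring = on_cart,
    treatment_total = waiting + on_cart
  )
}

#' Build the 6-month state trajectory over the hospitalization horizon
#'
#' For one patient: at the start of each 6-month interval of the horizon
#' (default 24 months from model entry), whether the patient is on cART and
#' their CD4 count — declining while waiting, reconstituting after
#' initiation. Initiation happens at the measurement itself, so the interval
#' beginning at the initiation time is on treatment.
#'
#' @param baseline_cd4 CD4 at entry, cells/uL.
#' @param wait_years Waiting time before initiation (0 for Scenario A).
#' @param cd4_start CD4 at initiation.
#' @param decline_per_period Pre-treatment decline, cells/uL per period.
#' @param params A `cea_parameters` object.
#' @return A tibble with one row per interval: `t_start` (years), `on_cart`,
#'   `cd4`, `stratum`.
#' @export
scenario_trajectory <- function(baseline_cd4, wait_years, cd4_start,
                                decline_per_period = 45.75,
                                params = cea_parameters()) {
  h <- params$measurement_interval
  n_int <- round(params$hospitalization_horizon / h)
  t <- (seq_len(n_int) - 1) * h
  on <- t >= wait_years
  cd4 <- ifelse(on,
                on_treatment_cd4(cd4_start, pmax(t - wait_years, 0),
                                 params$decline$reconstitution_rate_year1),
                pmax(baseline_cd4 - decline_per_period * (t / h), 0))
  tibble::tibble(
    t_start = t,
    on_cart = on,
    cd4 = cd4,
    stratum = ifelse(cd4 > params$inpatient$stratum_split,
                     "cd4_gt_350", "cd4_201_350")
  )
}

#' Hospitalization cost over the fixed horizon
#'
#' Expected cost of inpatient days over the hospitalization horizon (24
#' months from model entry, in four 6-month intervals, for both scenarios):
#' each interval contributes `interval_length x days_per_year(state) x
#' cost_per_day`, discounted at the interval midpoint. The state (CD4
#' stratum, on/off cART) is the state at the interval's start.
#'
#' @param trajectory A tibble as returned by [scenario_trajectory()]; must
#'   cover the whole horizon.
#' @param params A `cea_parameters` object.
#' @return Cost in USD.
#'
#' @examples
#' p <- cea_parameters()
#' tr <- scenario_trajectory(305, wait_years = 1, cd4_start = 213.5, 45.75, p)
#' hospitalization_cost(tr, p)
#' @export
hospitalization_cost <- function(trajectory, params = cea_parameters()) {
  h <- params$measurement_interval
  n_int <- round(params$hospitalization_horizon / h)
  if (nrow(trajectory) < n_int) {
    stop("trajectory must cover the full hospitalization horizon (",
         n_int, " intervals)", call. = FALSE)
  }
  trajectory <- trajectory[seq_len(n_int), ]
  tots <- inpatient_day_totals(params)
  days <- unname(tots[paste(trajectory$stratum, trajectory$on_cart)])
  rate <- params$discount$annual_rate
  sum(h * days * params$costs$cost_per_inpatient_day *
        discount_factor(trajectory$t_start + h / 2, rate))
}

# vectorised hospitalization cost over cohorts (same rule as
# hospitalization_cost(), closed over the 4-interval horizon)
hospitalization_cost_vec <- function(baseline_cd4, wait_years, cd4_start,
                                     decline_per_period, params) {
  h <- params$measurement_interval
  n_int <- round(params$hospitalization_horizon / h)
  tots <- inpatient_day_totals(params)
  d_on_lo <- tots[["cd4_201_350 TRUE"]]
  d_off_lo <- tots[["cd4_201_350 FALSE"]]
  d_on_hi <- tots[["cd4_gt_350 TRUE"]]
  d_off_hi <- tots[["cd4_gt_350 FALSE"]]
  rate <- params$discount$annual_rate
  cpd <- params$costs$cost_per_inpatient_day
  split <- params$inpatient$stratum_split
  recon <- params$decline$reconstitution_rate_year1
  n <- max(length(baseline_cd4), length(wait_years), length(cd4_start),
           length(decline_per_period))
  baseline_cd4 <- rep_len(baseline_cd4, n)
  wait_years <- rep_len(wait_years, n)
  cd4_start <- rep_len(cd4_start, n)
  decline_per_period <- rep_len(decline_per_period, n)
  total <- numeric(n)
  for (i in seq_len(n_int)) {
    t <- (i - 1) * h
    on <- t >= wait_years
    cd4 <- ifelse(on,
                  cd4_start + recon * pmin(pmax(t - wait_years, 0), 1),
                  pmax(baseline_cd4 - decline_per_period * (t / h), 0))
    hi <- cd4 > split
    days <- ifelse(hi, ifelse(on, d_on_hi, d_off_hi),
                   ifelse(on, d_on_lo, d_off_lo))
    total <- total + h * days * cpd * discount_factor(t + h / 2, rate)
  }
  total
}

#' Full cost breakdown for one scenario
#'
#' Assembles the three cost components of a scenario — waiting-period
#' monitoring, lifetime cART + monitoring, and hospitalization over the
#' fixed horizon — and their sum (the scenario's net cost).
#'
#' @param baseline_cd4 CD4 at entry, cells/uL.
#' @param wait_years Waiting time before initiation (0 for Scenario A).
#' @param cd4_start CD4 at initiation (equals `baseline_cd4` for Scenario A).
#' @param post_start_life_years Undiscounted life-years on treatment.
#' @param decline_per_period Pre-treatment decline, cells/uL per period.
#' @param params A `cea_parameters` object.
#' @return A tibble with `waiting_monitoring`, `cart_and_monitoring`,
#'   `hospitalization`, `net` (USD), one row per input.
#' @export
scenario_cost <- function(baseline_cd4, wait_years, cd4_start,
                          post_start_life_years,
                          decline_per_period = 45.75,
                          params = cea_parameters()) {
  treat <- lifetime_treatment_cost(wait_years, post_start_life_years, params)
  hosp <- hospitalization_cost_vec(baseline_cd4, wait_years, cd4_start,
                                   decline_per_period, params)
  tibble::tibble(
    waiting_monitoring = treat$waiting_monitoring,
    cart_and_monitoring = treat$cart_and_monitoring,
    hospitalization = hosp,
    net = treat$treatment_total + hosp
  )
}
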