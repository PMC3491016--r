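#' Baseline CD4 bins of the eligible cohort
#'
#' Partitions the eligibility window (250-350 cells/uL) into ten 10-cell
#' bins, 250-259 through 340-350, with midpoints `low + 5`.
#'
#' @param params A `cea_parameters` object (only `$cd4_range` is used).
#' @return A tibble with columns `bin`, `low`, `high`, `midpoint`.
#' @export
cd4_bins <- function(params = cea_parameters()) {
  lo <- params$cd4_range[1]
  hi <- params$cd4_range[2]
  low <- seq(lo, hi - 10, by = 10)
  high <- pmin(low + 9, hi)
  high[length(high)] <- hi
  tibble::tibble(
    bin = sprintf("%d-%d", low, high),
    low = low,
    high = high,
    midpoint = low + 5
  )
}

#' Evaluate both treatment scenarios for a set of patients
#'
#' The core pipeline. For each patient (a baseline CD4 count and a 6-month
#' CD4 decline rate) it evaluates:
#'
#' * **Scenario A** (immediate initiation): life expectancy at the baseline
#'   CD4, its discounted value, its disability-weighted (YLD) mass, and the
#'   cost breakdown (treatment + hospitalization).
#' * **Scenario B** (deferred initiation): the waiting time under biannual
#'   monitoring, life expectancy = wait + life expectancy at the initiation
#'   CD4, discounted and disability-weighted values, and costs including
#'   waiting-period monitoring.
#' * The comparison: YLL (difference in discounted life expectancy), signed
#'   YLD difference, DALYs averted, incremental cost, and the per-patient
#'   cost per DALY averted.
#'
#' @param data A data frame with columns `baseline_cd4` (cells/uL) and
#'   `decline_per_period` (cells/uL per 6 months).
#' @param params A `cea_parameters` object.
#' @return The input tibble augmented with columns `a_*` (Scenario A),
#'   `b_*` (Scenario B), `yll`, `yld`, `daly_averted`, `incremental_cost`,
#'   and `icer`.
#'
#' @examples
#' evaluate_patients(
#'   tibble::tibble(baseline_cd4 = c(255, 345), decline_per_period = 45.75)
#' )
#' @export
evaluate_patients <- function(data, params = cea_parameters()) {
  stopifnot(all(c("baseline_cd4", "decline_per_period") %in% names(data)))
  validate_parameters(params)
  rate <- params$discount$annual_rate
  conv <- params$discount$convention
  dw <- params$disability

  dwy <- function(length, delay) {
    disability_weighted_years(length, delay, rate, conv,
                              dw$hiv_weight, dw$aids_weight,
                              dw$aids_years_before_death)
  }

  cd4 <- data$baseline_cd4
  dec <- data$decline_per_period

  # Scenario A: immediate initiation at the baseline CD4
  a_le <- life_expectancy(cd4, params)
  a_dle <- discount_years(a_le, 0, rate, conv)
  a_yld <- dwy(a_le, 0)
  a_cost <- scenario_cost(cd4, 0, cd4, a_le, dec, params)

  # Scenario B: wait for the first biannual measurement below threshold
  w <- wait_to_initiation(cd4, dec, params$cd4_threshold,
                          params$measurement_interval)
  b_le_post <- life_expectancy(pmax(w$cd4_at_initiation, 1), params)
  b_le <- w$wait_years + b_le_post
  b_dle <- discount_years(w$wait_years, 0, rate, conv) +
    discount_years(b_le_post, w$wait_years, rate, conv)
  b_yld <- dwy(b_le, 0)
  b_cost <- scenario_cost(cd4, w$wait_years, w$cd4_at_initiation,
                          b_le_post, dec, params)

  yll <- a_dle - b_dle
  yld <- b_yld - a_yld
  daly <- yll + yld

  dplyr::mutate(
    tibble::as_tibble(data),
    a_life_expectancy = a_le,
    a_discounted_le = a_dle,
    a_yld_mass = a_yld,
    a_cost_treatment = a_cost$cart_and_monitoring,
    a_cost_hospitalization = a_cost$hospitalization,
    a_cost_net = a_cost$net,
    b_wait_years = w$wait_years,
    b_cd4_at_initiation = w$cd4_at_initiation,
    b_life_expectancy = b_le,
    b_discounted_le = b_dle,
    b_yld_mass = b_yld,
    b_cost_waiting = b_cost$waiting_monitoring,
    b_cost_treatment = b_cost$cart_and_monitoring,
    b_cost_hospitalization = b_cost$hospitalization,
    b_cost_net = b_cost$net,
    yll = yll,
    yld = yld,
    daly_averted = daly,
    incremental_cost = a_cost$net - b_cost$net,
    icer = ifelse(daly == 0, NA_real_, (a_cost$net - b_cost$net) / daly)
  )
}

#' Evaluate the deterministic ten-bin cohort
#'
#' Runs [evaluate_patients()] at the ten bin midpoints with a common CD4
#' decline rate (a percentile of the published decline distribution).
#'
#' @param params A `cea_parameters` object.
#' @param decline Decline percentile: `"median"` (base case), `"q25"`, or
#'   `"q75"`.
#' @return A tibble with one row per bin: the bin columns of [cd4_bins()]
#'   plus all [evaluate_patients()] outcome columns.
#' @export
evaluate_cohort <- function(params = cea_parameters(),
                            decline = c("median", "q25", "q75")) {
  decline <- match.arg(decline)
  d <- decline_at_percentile(params$decline, decline)
  bins <- cd4_bins(params)
  res <- evaluate_patients(
    tibble::tibble(baseline_cd4 = bins$midpoint, decline_per_period = d),
    params
  )
  dplyr::bind_cols(bins, dplyr::select(res, -"baseline_cd4"))
}

#' DALYs averted by early versus deferred initiation
#'
#' YLL is the difference in discounted life expectancy between the two
#' scenarios; YLD is the signed difference in disability-weighted discounted
#' life-years (negative when the early scenario's longer life carries more
#' disability-weighted time); DALYs averted = YLL + YLD.
#'
#' @param a,b Scenario outcomes: lists or one-row data frames with fields
#'   `discounted_le` and `yld_mass`.
#' @return A tibble with columns `yll`, `yld`, `daly`.
#' @export
daly_averted <- function(a, b) {
  tibble::tibble(
    yll = a$discounted_le - b$discounted_le,
    yld = b$yld_mass - a$yld_mass,
    daly = (a$discounted_le - b$discounted_le) + (b$yld_mass - a$yld_mass)
  )
}

#' Incremental cost-effectiveness ratio
#'
#' @param incremental_cost Incremental cost, USD.
#' @param daly_averted DALYs averted (nonzero).
#' @return USD per DALY averted.
#' @export
icer <- function(incremental_cost, daly_averted) {
  if (any(daly_averted == 0)) {
    stop("ICER undefined when DALYs averted is zero", call. = FALSE)
  }
  incremental_cost / daly_averted
}

#' Classify an ICER against the per-capita-GDP thresholds
#'
#' WHO convention: an intervention is "highly cost-effective" below one
#' times per-capita GDP per DALY averted, "cost-effective" below three
#' times, and "not cost-effective" otherwise (boundaries excluded from the
#' better class).
#'
#' @param icer USD per DALY averted (`>= 0`, vectorised).
#' @param gdp_per_capita Annual per-capita GDP, USD (default $490).
#' @return Character vector of classifications.
#'
#' @examples
#' classify_cost_effectiveness(c(260, 490, 1500))
#' @export
classify_cost_effectiveness <- function(icer, gdp_per_capita = 490) {
  if (any(icer < 0)) stop("icer must be non-negative", call. = FALSE)
  dplyr::case_when(
    icer < gdp_per_capita ~ "highly cost-effective",
    icer < 3 * gdp_per_capita ~ "cost-effective",
    TRUE ~ "not cost-effective"
  )
}

#' Roll up the ten-bin results into the lowest/mean/highest summary
#'
#' Reproduces the paper-style summary table: the lowest (250-259) and
#' highest (340-350) bins verbatim and an unweighted mean row over the ten
#' bins (the cohort's baseline CD4 is uniform across bins). Each row's cost
#' per DALY averted is the ratio of that row's own aggregates — for the mean
#' row, mean incremental cost over mean DALYs averted, not the mean of
#' per-bin ratios. Rows with non-positive DALYs averted or cost savings are
#' flagged as dominant/dominated rather than given a signed ICER.
#'
#' @param bin_results A ten-bin tibble from [evaluate_cohort()] with the
#'   base bin partition.
#' @param params The `cea_parameters` the bins were evaluated under.
#' @return An object of class `cea_summary` with components `rows` (tibble:
#'   `row`, `bin`, outcome columns, `icer`, `dominance`), `bins`,
#'   `classification`, and `params`. Has [tidy()], [glance()], `print()`
#'   and [render_table2()] methods.
#' @export
cea_summary <- function(bin_results, params = cea_parameters()) {
  expected <- cd4_bins(params)
  if (!identical(nrow(bin_results), nrow(expected)) ||
      !all(bin_results$low == expected$low & bin_results$high == expected$high)) {
    stop("bin_results must contain exactly the base CD4 bin partition",
         call. = FALSE)
  }
  num_cols <- names(bin_results)[vapply(bin_results, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("low", "high", "midpoint", "icer"))

  mk_row <- function(label, values, bin_label) {
    tibble::as_tibble(c(list(row = label, bin = bin_label), values))
  }
  low_row <- mk_row("lowest", as.list(bin_results[1, num_cols]), bin_results$bin[1])
  n <- nrow(bin_results)
  high_row <- mk_row("highest", as.list(bin_results[n, num_cols]), bin_results$bin[n])
  mean_row <- mk_row("mean", as.list(colMeans(bin_results[num_cols])),
                     sprintf("%d-%d", params$cd4_range[1], params$cd4_range[2]))
  rows <- dplyr::bind_rows(low_row, mean_row, high_row)
  rows <- dplyr::mutate(
    rows,
    dominance = dplyr::case_when(
      .data$daly_averted > 0 & .data$incremental_cost <= 0 ~ "dominant",
      .data$daly_averted <= 0 & .data$incremental_cost >= 0 ~ "dominated",
      .default = NA_character_
    ),
    icer = ifelse(is.na(.data$dominance) & .data$daly_averted != 0,
                  .data$incremental_cost / .data$daly_averted, NA_real_)
  )
  mean_icer <- rows$icer[rows$row == "mean"]
  structure(
    list(
      rows = rows,
      bins = bin_results,
      classification = if (!is.na(mean_icer) && mean_icer >= 0) {
        classify_cost_effectiveness(mean_icer, params$gdp_per_capita)
      } else {
        rows$dominance[rows$row == "mean"]
      },
      params = params
    ),
    class = "cea_summary"
  )
}

#' @export
print.cea_summary <- function(x, ...) {
  cat("Early vs deferred cART initiation - cost-effectiveness summary\n\n")
  print(render_table2(x), n = Inf)
  cat(sprintf("\nMean cost per DALY averted: $%.0f (%s at GDP/capita $%g)\n",
              x$rows$icer[x$rows$row == "mean"], x$classification,
              x$params$gdp_per_capita))
  invisible(x)
}

#' @rdname cea_summary
#' @param x A `cea_summary` object.
#' @param ... Unused.
#' @method tidy cea_summary
#' @export
tidy.cea_summary <- function(x, ...) {
  x$rows
}

#' @rdname cea_summary
#' @method glance cea_summary
#' @export
glance.cea_summary <- function(x, ...) {
  m <- x$rows[x$rows$row == "mean", ]
  tibble::tibble(
    icer = m$icer,
    daly_averted = m$daly_averted,
    incremental_cost = m$incremental_cost,
    yll = m$yll,
    yld = m$yld,
    classification = x$classification,
    n_bins = nrow(x$bins)
  )
}

#' @rdname cea_summary
#' @param object A `cea_summary` object.
#' @method autoplot cea_summary
#' @export
autoplot.cea_summary <- function(object, ...) {
  long <- object$bins |>
    dplyr::select("midpoint", "yll", "yld", "daly_averted") |>
    tidyr::pivot_longer(-"midpoint", names_to = "component", values_to = "years")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$midpoint, y = .data$years,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "Baseline CD4 bin midpoint (cells/µL)",
      y = "Years per patient",
      colour = NULL,
      title = "DALYs averted by early initiation, by baseline CD4 bin"
    ) +
    ggplot2::theme_minimal()
}
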