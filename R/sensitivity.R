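#' One-way sensitivity ranges
#'
#' The eight tornado parameters and their bounds: annual cART drug cost
#' (AC1, $100-$300), annual cART maintenance cost (AC2, $50-$200), a joint
#' scale on all inpatient-day rates (IH, -50%/+50%), the daily
#' hospitalization cost (HC, $15.74-$47.22), the discount rate (DR, 0%-6%),
#' the 6-month CD4 decline (CD4, 30.65-62.35, i.e. the quartiles of the
#' decline distribution), the annual pre-treatment monitoring cost (AC3,
#' $0-$150), and a joint scale on the life-expectancy anchors (LE,
#' -15%/+15%).
#'
#' @param params A `cea_parameters` object (base values are read from it).
#' @return A tibble with columns `parameter_id`, `label`, `base`, `low`,
#'   `high`.
#' @export
sensitivity_ranges <- function(params = cea_parameters()) {
  tibble::tibble(
    parameter_id = c("cart_drug", "cart_maintenance", "inpatient_days_scale",
                     "cost_per_day", "discount_rate", "cd4_decline",
                     "waiting_cost", "life_expectancy_scale"),
    label = c("AC1", "AC2", "IH", "HC", "DR", "CD4", "AC3", "LE"),
    base = c(params$costs$cart_drug_annual,
             params$costs$cart_maintenance_annual,
             1,
             params$costs$cost_per_inpatient_day,
             params$discount$annual_rate,
             params$decline$median_per_period,
             params$costs$waiting_total_annual,
             1),
    low = c(100, 50, 0.5, 15.74, 0, params$decline$q25_per_period, 0, 0.85),
    high = c(300, 200, 1.5, 47.22, 0.06, params$decline$q75_per_period, 150, 1.15)
  )
}

#' Set one sensitivity parameter to a value
#'
#' Returns a copy of `params` with a single tornado parameter replaced (or,
#' for the scale-type parameters `inpatient_days_scale` and
#' `life_expectancy_scale`, with all underlying values multiplied).
#' Accounting totals are kept consistent: changing a cART cost component
#' recomputes the treatment total, and changing the waiting total rescales
#' its components.
#'
#' @param params A `cea_parameters` object.
#' @param parameter_id One of the ids in [sensitivity_ranges()].
#' @param value The new value (or scale factor).
#' @return A validated `cea_parameters` object.
#' @export
perturb_parameters <- function(params, parameter_id, value) {
  p <- params
  switch(parameter_id,
    cart_drug = {
      p$costs$cart_drug_annual <- value
      p$costs$treatment_total_annual <- value + p$costs$cart_maintenance_annual
    },
    cart_maintenance = {
      p$costs$cart_maintenance_annual <- value
      p$costs$treatment_total_annual <- p$costs$cart_drug_annual + value
    },
    inpatient_days_scale = {
      p$inpatient$rates$days_per_year <- p$inpatient$rates$days_per_year * value
    },
    cost_per_day = {
      p$costs$cost_per_inpatient_day <- value
    },
    discount_rate = {
      p$discount$annual_rate <- value
    },
    cd4_decline = {
      p$decline$median_per_period <- value
      p$decline$q25_per_period <- min(p$decline$q25_per_period, value)
      p$decline$q75_per_period <- max(p$decline$q75_per_period, value)
    },
    waiting_cost = {
      old <- p$costs$waiting_total_annual
      scale <- if (old > 0) value / old else 0
      p$costs$waiting_components <- lapply(p$costs$waiting_components,
                                           function(c) c * scale)
      p$costs$waiting_total_annual <- value
    },
    life_expectancy_scale = {
      p$anchors$life_expectancy <- p$anchors$life_expectancy * value
    },
    stop("unknown sensitivity parameter: '", parameter_id, "'", call. = FALSE)
  )
  validate_parameters(p)
  p
}

# mean-row ICER (and dominance state) of a full model run
mean_row_icer <- function(params, decline = "median") {
  s <- cea_summary(evaluate_cohort(params, decline), params)
  m <- s$rows[s$rows$row == "mean", ]
  list(icer = m$icer, dominance = m$dominance)
}

#' One-way sensitivity analysis for a single parameter
#'
#' Re-runs the full mean-row ICER with one parameter set to its low bound,
#' then to its high bound, the rest held at base case.
#'
#' @param params A `cea_parameters` object (the base case).
#' @param parameter_id One of the ids in [sensitivity_ranges()].
#' @param ranges A ranges tibble as from [sensitivity_ranges()].
#' @return A one-row tibble: `parameter_id`, `label`, `low`, `high`,
#'   `icer_low`, `icer_high`, `span`, and dominance flags (`NA` ICER with a
#'   label when a bound produces a dominant/dominated comparison).
#' @export
one_way <- function(params, parameter_id, ranges = sensitivity_ranges(params)) {
  rng <- ranges[ranges$parameter_id == parameter_id, ]
  if (nrow(rng) != 1) {
    stop("unknown sensitivity parameter: '", parameter_id, "'", call. = FALSE)
  }
  at <- function(value) mean_row_icer(perturb_parameters(params, parameter_id, value))
  lo <- at(rng$low)
  hi <- at(rng$high)
  tibble::tibble(
    parameter_id = rng$parameter_id,
    label = rng$label,
    low = rng$low,
    high = rng$high,
    icer_low = lo$icer,
    icer_high = hi$icer,
    dominance_low = lo$dominance,
    dominance_high = hi$dominance,
    span = abs(hi$icer - lo$icer)
  )
}

#' Tornado analysis over all sensitivity parameters
#'
#' Runs [one_way()] for every parameter in `ranges` and orders the entries
#' by descending ICER span — the tornado-plot ordering.
#'
#' @inheritParams one_way
#' @return A tibble of class `cea_tornado`, one row per parameter, sorted by
#'   `span` (descending), with the base-case ICER in attribute
#'   `"base_icer"`. Has an [autoplot()] method.
#'
#' @examples
#' \donttest{
#' tor <- tornado(cea_parameters())
#' tor$label           # "AC1", "AC2", ... by decreasing influence
#' autoplot(tor)
#' }
#' @export
tornado <- function(params = cea_parameters(),
                    ranges = sensitivity_ranges(params)) {
  entries <- purrr::map(ranges$parameter_id, one_way,
                        params = params, ranges = ranges) |>
    purrr::list_rbind() |>
    dplyr::arrange(dplyr::desc(.data$span))
  base <- mean_row_icer(params)$icer
  structure(entries, base_icer = base,
            class = c("cea_tornado", class(entries)))
}

#' @rdname tornado
#' @param object A `cea_tornado` tibble.
#' @param ... Unused.
#' @method autoplot cea_tornado
#' @export
autoplot.cea_tornado <- function(object, ...) {
  base <- attr(object, "base_icer")
  dat <- dplyr::mutate(
    tibble::as_tibble(object),
    label = factor(.data$label, levels = rev(.data$label)),
    lo = pmin(.data$icer_low, .data$icer_high),
    hi = pmax(.data$icer_low, .data$icer_high)
  )
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$lo, xend = .data$hi, yend = .data$label),
      linewidth = 5, colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(
      x = "Cost per DALY averted (USD)",
      y = NULL,
      title = "One-way sensitivity of the ICER",
      subtitle = sprintf("Dashed line: base case $%.0f per DALY averted", base)
    ) +
    ggplot2::theme_minimal()
}
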