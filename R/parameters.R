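#' Model parameters for the early-vs-deferred cART cost-effectiveness model
#'
#' Builds the complete, validated set of model inputs: life-expectancy
#' anchors, the pre-treatment CD4 decline model, disability weights,
#' inpatient-day rates by CD4 stratum and treatment status, unit costs, the
#' discounting specification, and the cohort conventions (eligibility window,
#' measurement interval, hospitalization horizon, GDP threshold).
#'
#' Defaults are the base-case values of the source cost study (2011 USD).
#' Overrides are supplied as nested lists mirroring the parameter sections,
#' e.g. `cea_parameters(discount = list(annual_rate = 0))`. Unknown keys are
#' an error: the parameter file is the model's single source of truth and is
#' validated loudly. When `cart_drug_annual` or `cart_maintenance_annual` is
#' overridden without `treatment_total_annual`, the total is recomputed (and
#' likewise for the waiting-cost components), so the accounting invariants
#' hold by construction.
#'
#' @param ... Named overrides, one per parameter section (`anchors`,
#'   `decline`, `disability`, `inpatient`, `costs`, `discount`,
#'   `cd4_threshold`, `cd4_range`, `measurement_interval`,
#'   `hospitalization_horizon`, `gdp_per_capita`).
#'
#' @return An object of class `cea_parameters`: a named list of parameter
#'   sections. Scalar sections are plain values; `anchors` and
#'   `inpatient$rates` are tibbles.
#'
#' @examples
#' p <- cea_parameters()
#' p$costs$treatment_total_annual
#' p0 <- cea_parameters(discount = list(annual_rate = 0))
#' @export
cea_parameters <- function(...) {
  overrides <- list(...)
  base <- parameter_defaults()
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    # recompute accounting totals unless explicitly supplied
    co <- overrides$costs
    base <- merge_parameters(base, overrides, path = "")
    if (!is.null(co)) {
      if (any(c("cart_drug_annual", "cart_maintenance_annual") %in% names(co)) &&
          !"treatment_total_annual" %in% names(co)) {
        base$costs$treatment_total_annual <-
          base$costs$cart_drug_annual + base$costs$cart_maintenance_annual
      }
      if ("waiting_components" %in% names(co) && !"waiting_total_annual" %in% names(co)) {
        base$costs$waiting_total_annual <-
          round(sum(unlist(base$costs$waiting_components)), 2)
      }
    }
  }
  structure(base, class = c("cea_parameters", "list"))
}

#' @rdname cea_parameters
#' @export
default_parameters <- function() {
  validate_parameters(cea_parameters())
}

# Base-case inputs (2011 USD). Anchors are the published conditional life
# expectancies placed at the midpoints of their CD4 source strata; the
# lowest anchor (25, 7.9) keeps the interpolator defined below 125 cells/uL
# even though the base-case cohort never reaches it.
parameter_defaults <- function() {
  list(
    anchors = tibble::tibble(
      cd4_midpoint = c(25, 125, 275),
      life_expectancy = c(7.9, 9.6, 19.3)
    ),
    decline = list(
      median_per_period = 45.75,
      q25_per_period = 30.65,
      q75_per_period = 62.35,
      period_years = 0.5,
      reconstitution_rate_year1 = 114
    ),
    disability = list(
      hiv_weight = 0.123,
      aids_weight = 0.5,
      aids_years_before_death = 1
    ),
    inpatient = list(
      stratum_split = 350,
      rates = tibble::tibble(
        stratum = rep(c("cd4_201_350", "cd4_gt_350"), each = 4),
        on_cart = rep(c(TRUE, TRUE, FALSE, FALSE), 2),
        oi = rep(c(TRUE, FALSE), 4),
        days_per_year = c(0.52, 0.39, 10.8, 3.0, 0.37, 0.14, 5.7, 1.9)
      )
    ),
    costs = list(
      cart_drug_annual = 192.44,
      cart_maintenance_annual = 113.40,
      treatment_total_annual = 305.84,
      waiting_components = list(
        clinic_personnel = 14.32,
        lab = 35.04,
        other_medication = 33.72,
        radiology = 1.68
      ),
      waiting_total_annual = 84.76,
      cost_per_inpatient_day = 31.48
    ),
    discount = list(
      annual_rate = 0.03,
      convention = "semiannual_midperiod"
    ),
    cd4_threshold = 250,
    cd4_range = c(250, 350),
    measurement_interval = 0.5,
    hospitalization_horizon = 2,
    gdp_per_capita = 490
  )
}

# strict recursive merge: unknown keys fail loudly
merge_parameters <- function(base, over, path) {
  for (nm in names(over)) {
    full <- paste0(path, nm)
    if (!nm %in% names(base)) {
      stop("unknown parameter key: '", full, "'", call. = FALSE)
    }
    val <- over[[nm]]
    if (is.data.frame(base[[nm]])) {
      if (is.list(val) && !is.data.frame(val)) val <- dplyr::bind_rows(val)
      if (!identical(sort(names(val)), sort(names(base[[nm]])))) {
        stop("replacement for '", full, "' must have columns: ",
             paste(names(base[[nm]]), collapse = ", "), call. = FALSE)
      }
      base[[nm]] <- tibble::as_tibble(val)[names(base[[nm]])]
    } else if (is.list(base[[nm]])) {
      if (!is.list(val)) {
        stop("'", full, "' must be a list of overrides", call. = FALSE)
      }
      base[[nm]] <- merge_parameters(base[[nm]], val, paste0(full, "$"))
    } else {
      base[[nm]] <- val
    }
  }
  base
}

#' Validate a parameter object
#'
#' Checks every structural and accounting invariant of the model inputs and
#' fails with a message naming the violated invariant. Called by
#' [load_parameters()] and by the model entry points; exported so that
#' hand-built parameter objects can be checked too.
#'
#' @param params A `cea_parameters` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  fail <- function(...) stop("invalid parameters: ", ..., call. = FALSE)

  a <- params$anchors
  if (nrow(a) < 2) fail("at least two life-expectancy anchors are required")
  if (any(a$cd4_midpoint <= 0)) fail("anchor cd4_midpoint must be > 0")
  if (any(a$life_expectancy <= 0)) fail("anchor life_expectancy must be > 0")
  if (any(diff(a$cd4_midpoint) <= 0) || any(diff(a$life_expectancy) <= 0)) {
    fail("anchors must be strictly increasing in cd4_midpoint and life_expectancy")
  }

  d <- params$decline
  if (!(0 < d$q25_per_period && d$q25_per_period <= d$median_per_period &&
        d$median_per_period <= d$q75_per_period)) {
    fail("decline quantiles must satisfy 0 < q25 <= median <= q75")
  }
  if (d$period_years <= 0) fail("decline period_years must be > 0")
  if (d$reconstitution_rate_year1 < 0) fail("reconstitution_rate_year1 must be >= 0")

  dw <- params$disability
  if (!(0 <= dw$hiv_weight && dw$hiv_weight < dw$aids_weight && dw$aids_weight <= 1)) {
    fail("disability weights must satisfy 0 <= hiv_weight < aids_weight <= 1")
  }
  if (dw$aids_years_before_death < 0) fail("aids_years_before_death must be >= 0")

  r <- params$inpatient$rates
  if (any(r$days_per_year < 0)) fail("inpatient days_per_year must be >= 0")
  chk <- tidyr::pivot_wider(r, names_from = "on_cart", values_from = "days_per_year")
  if (any(chk$`FALSE` < chk$`TRUE`)) {
    fail("off-cART inpatient rate must be >= on-cART rate within each stratum x OI cell")
  }

  co <- params$costs
  scalars <- c(co$cart_drug_annual, co$cart_maintenance_annual,
               co$treatment_total_annual, unlist(co$waiting_components),
               co$waiting_total_annual, co$cost_per_inpatient_day)
  if (any(scalars < 0)) fail("all costs must be >= 0")
  if (abs(co$treatment_total_annual -
          (co$cart_drug_annual + co$cart_maintenance_annual)) > 0.005) {
    fail("treatment_total_annual must equal cart_drug_annual + ",
         "cart_maintenance_annual to the cent")
  }
  if (abs(co$waiting_total_annual - sum(unlist(co$waiting_components))) > 0.005) {
    fail("waiting_total_annual must equal the sum of waiting_components to the cent")
  }

  ds <- params$discount
  if (ds$annual_rate < 0 || ds$annual_rate > 0.20) {
    fail("discount annual_rate must lie in [0, 0.20]")
  }
  if (!ds$convention %in% discount_conventions()) {
    fail("discount convention must be one of: ",
         paste(discount_conventions(), collapse = ", "))
  }

  if (params$cd4_threshold < 0 || params$cd4_threshold > params$cd4_range[1]) {
    fail("cd4_threshold must lie in [0, cd4_range[1]]")
  }
  k <- params$hospitalization_horizon / params$measurement_interval
  if (params$hospitalization_horizon <= 0 || abs(k - round(k)) > 1e-9) {
    fail("hospitalization_horizon must be a positive multiple of measurement_interval")
  }
  invisible(params)
}

#' Load model parameters from a YAML configuration file
#'
#' Reads a YAML file of overrides (same nested structure as
#' [cea_parameters()]), merges it over the base-case defaults, and validates
#' the result. Keys omitted from the file keep their base-case values;
#' unknown keys are a configuration error.
#'
#' @param path Path to a YAML file (or a file connection).
#' @return A validated `cea_parameters` object.
#' @seealso [parameters_json()] for re-emitting the resolved parameters as
#'   JSON provenance.
#' @export
load_parameters <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  params <- do.call(cea_parameters, cfg)
  validate_parameters(params)
  params
}

#' Serialize parameters to JSON for provenance
#'
#' Every results bundle written by [run_cea()] embeds the fully-resolved
#' parameter set so a run can be reproduced from its outputs alone.
#'
#' @param params A `cea_parameters` object.
#' @param path Optional path; when supplied the JSON is written there.
#' @return The JSON string (invisibly when `path` is given).
#' @export
parameters_json <- function(params, path = NULL) {
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("<cea_parameters>\n")
  cat("  anchors:   ", paste(sprintf("(%g, %.2f yr)", x$anchors$cd4_midpoint,
                                     x$anchors$life_expectancy), collapse = " "), "\n")
  cat(sprintf("  decline:    %.2f cells/uL per %.1f yr (IQR %.2f-%.2f)\n",
              x$decline$median_per_period, x$decline$period_years,
              x$decline$q25_per_period, x$decline$q75_per_period))
  cat(sprintf("  disability: HIV %.3f, AIDS %.2f (terminal %g yr)\n",
              x$disability$hiv_weight, x$disability$aids_weight,
              x$disability$aids_years_before_death))
  cat(sprintf("  costs:      cART+monitoring $%.2f/yr, waiting $%.2f/yr, bed day $%.2f\n",
              x$costs$treatment_total_annual, x$costs$waiting_total_annual,
              x$costs$cost_per_inpatient_day))
  cat(sprintf("  discount:   %.1f%% (%s)\n", 100 * x$discount$annual_rate,
              x$discount$convention))
  cat(sprintf("  cohort:     CD4 %g-%g, threshold %g, horizon %g yr\n",
              x$cd4_range[1], x$cd4_range[2], x$cd4_threshold,
              x$hospitalization_horizon))
  invisible(x)
}
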