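#' Render the summary as a paper-style comparison table
#'
#' Formats a [cea_summary()] as the familiar two-scenario table: one row per
#' (quantity, CD4 row) pair with "Start (Scenario A)" and "Wait (Scenario
#' B)" columns. Years are printed to 2 decimals; dollar amounts to the whole
#' dollar with thousands separators; the cost per DALY averted to the
#' dollar. Rows flagged dominant/dominated print the flag in place of the
#' ICER. The deferred arm's lifetime cost column folds waiting-period
#' monitoring into "Lifetime Cost, cART + Monitoring", matching the
#' conventional presentation; the components stay separable in the
#' underlying summary.
#'
#' @param summary A `cea_summary` object.
#' @return A tibble with character columns `quantity`, `baseline_cd4`,
#'   `scenario_a`, `scenario_b`.
#' @export
render_table2 <- function(summary) {
  if (!inherits(summary, "cea_summary") || nrow(summary$rows) == 0) {
    stop("render_table2() needs a non-empty cea_summary", call. = FALSE)
  }
  rows <- summary$rows
  yr <- function(x) sprintf("%.2f", x)
  usd <- function(x) paste0("$", formatC(round(x), format = "d", big.mark = ","))
  row_label <- function(r, b) {
    paste0(tools::toTitleCase(r), " (", b, ")")
  }
  one <- function(quantity, fa, fb, fmt) {
    tibble::tibble(
      quantity = quantity,
      baseline_cd4 = row_label(rows$row, rows$bin),
      scenario_a = if (is.null(fa)) "" else fmt(fa(rows)),
      scenario_b = if (is.null(fb)) "" else fmt(fb(rows))
    )
  }
  icer_cell <- ifelse(!is.na(rows$dominance), rows$dominance, usd(rows$icer))
  dplyr::bind_rows(
    one("Life Expectancy, in years",
        function(r) r$a_life_expectancy, function(r) r$b_life_expectancy, yr),
    one("Discounted Life Expectancy, in years",
        function(r) r$a_discounted_le, function(r) r$b_discounted_le, yr),
    one("YLL", NULL, function(r) r$yll, yr),
    one("YLD", NULL, function(r) r$yld, yr),
    one("DALY", NULL, function(r) r$daly_averted, yr),
    one("Lifetime Cost, cART + Monitoring",
        function(r) r$a_cost_treatment,
        function(r) r$b_cost_waiting + r$b_cost_treatment, usd),
    one("24 Months Hospitalization Cost",
        function(r) r$a_cost_hospitalization,
        function(r) r$b_cost_hospitalization, usd),
    one("Net Cost",
        function(r) r$a_cost_net, function(r) r$b_cost_net, usd),
    tibble::tibble(
      quantity = "Cost per DALY",
      baseline_cd4 = row_label(rows$row, rows$bin),
      scenario_a = icer_cell,
      scenario_b = ""
    )
  )
}

#' Run the full analysis and write a results bundle
#'
#' Orchestrates a complete run: resolves parameters (base case, a YAML
#' config, or a ready parameter object), evaluates the ten-bin cohort,
#' summarises it, and writes to `output_dir`:
#'
#' * `table2_replica.csv` — the formatted comparison table;
#' * `table2_replica.json` — the numeric summary rows;
#' * `waiting_table.csv` — per-bin waiting time and initiation CD4;
#' * `tornado.csv` — the one-way sensitivity table (unless
#'   `sensitivity = FALSE`);
#' * `cohort_summary.json` — microsimulation means/SEs (when
#'   `microsim = TRUE`);
#' * `parameters.json` — the resolved parameters, for provenance;
#' * `manifest.json` — run metadata: package version, seed, timestamp, and
#'   an MD5 checksum for every output file.
#'
#' @param output_dir Directory to write into (created if needed).
#' @param config Optional path to a YAML parameter file.
#' @param params Optional `cea_parameters` object (overrides `config`).
#' @param decline Decline percentile for the deterministic run.
#' @param sensitivity Run the tornado analysis? (default `TRUE`).
#' @param microsim Run the microsimulation validator? (default `FALSE`).
#' @param n_patients Cohort size for the microsimulation.
#' @param seed Seed for the microsimulation.
#' @return The run manifest (a list), invisibly. The summary object is in
#'   attribute `"summary"`.
#' @export
run_cea <- function(output_dir, config = NULL, params = NULL,
                    decline = c("median", "q25", "q75"),
                    sensitivity = TRUE, microsim = FALSE,
                    n_patients = 10000, seed = 1) {
  decline <- match.arg(decline)
  if (is.null(params)) {
    params <- if (is.null(config)) cea_parameters() else load_parameters(config)
  }
  validate_parameters(params)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  bins <- evaluate_cohort(params, decline)
  summ <- cea_summary(bins, params)

  files <- character()
  put <- function(name, writer) {
    path <- file.path(output_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }

  put("table2_replica.csv", function(p) {
    write.csv(render_table2(summ), p, row.names = FALSE)
  })
  put("table2_replica.json", function(p) {
    jsonlite::write_json(summ$rows, p, auto_unbox = TRUE, digits = NA)
  })
  put("waiting_table.csv", function(p) {
    write.csv(cohort_wait_summary(params, decline)$table, p, row.names = FALSE)
  })
  if (sensitivity) {
    put("tornado.csv", function(p) {
      write.csv(tibble::as_tibble(tornado(params)), p, row.names = FALSE)
    })
  }
  if (microsim) {
    put("cohort_summary.json", function(p) {
      ms <- microsimulate(sample_cohort(n_patients, params, seed), params)
      jsonlite::write_json(
        list(n = ms$n, seed = seed, summary = ms$summary,
             icer = ms$icer, icer_se = ms$icer_se),
        p, auto_unbox = TRUE, digits = NA
      )
    })
  }
  put("parameters.json", function(p) parameters_json(params, p))

  manifest <- list(
    package = "cartcea",
    version = as.character(packageVersion("cartcea")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    decline_percentile = decline,
    seed = if (microsim) seed else NULL,
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(output_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "summary") <- summ
  invisible(manifest)
}
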