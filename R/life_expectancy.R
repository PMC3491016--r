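#' Life expectancy at cART initiation, by baseline CD4 count
#'
#' Piecewise-linear interpolation of undiscounted life expectancy between the
#' published anchors (by default 7.9 yr at CD4 25, 9.6 yr at 125, 19.3 yr at
#' 275 cells/uL, each anchor placed at the midpoint of its source CD4
#' stratum). Above the top anchor the last segment's slope is extended
#' linearly with no cap (the cohort's upper bins require it); below the
#' bottom anchor the value is clamped at the bottom anchor rather than
#' extrapolated toward zero. The function is continuous and monotone
#' non-decreasing in CD4.
#'
#' @param cd4 Baseline CD4 count at initiation, cells/uL (vectorised, `> 0`).
#' @param params A `cea_parameters` object (only `$anchors` is used).
#' @return Numeric vector of undiscounted life expectancies in years.
#'
#' @examples
#' p <- cea_parameters()
#' life_expectancy(c(125, 275), p) # the anchors themselves
#' life_expectancy(255, p)         # 18.01 yr: lowest cohort bin midpoint
#' @export
life_expectancy <- function(cd4, params = cea_parameters()) {
  if (any(cd4 <= 0)) stop("cd4 must be positive", call. = FALSE)
  anchors <- params$anchors
  x <- anchors$cd4_midpoint
  y <- anchors$life_expectancy
  k <- length(x)
  out <- stats::approx(x, y, xout = pmin(pmax(cd4, x[1]), x[k]),
                       method = "linear", ties = "ordered")$y
  hi <- cd4 > x[k]
  if (any(hi)) {
    slope <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
    out[hi] <- y[k] + slope * (cd4[hi] - x[k])
  }
  out
}

#' Tabulate the life-expectancy curve
#'
#' Evaluates [life_expectancy()] on a CD4 grid (default 50 to 350 cells/uL
#' in 10-cell steps), the tabular form of the model's life-expectancy
#' figure.
#'
#' @param params A `cea_parameters` object.
#' @param cd4 CD4 grid to evaluate.
#' @return A tibble with columns `cd4` and `life_expectancy`.
#' @export
life_expectancy_table <- function(params = cea_parameters(),
                                  cd4 = seq(50, 350, by = 10)) {
  tibble::tibble(cd4 = cd4, life_expectancy = life_expectancy(cd4, params))
}

#' Plot the modeled life-expectancy curve
#'
#' @inheritParams life_expectancy_table
#' @return A ggplot object: life expectancy versus baseline CD4, with the
#'   anchors marked.
#' @export
plot_life_expectancy <- function(params = cea_parameters()) {
  tab <- life_expectancy_table(params)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$cd4, y = .data$life_expectancy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(
      data = params$anchors,
      ggplot2::aes(x = .data$cd4_midpoint, y = .data$life_expectancy),
      shape = 21, size = 2.5, fill = "white"
    ) +
    ggplot2::labs(
      x = "Baseline CD4 count at cART initiation (cells/µL)",
      y = "Life expectancy (years, undiscounted)",
      title = "Modeled life expectancy by baseline CD4 count"
    ) +
    ggplot2::theme_minimal()
}
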