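#' Discounting conventions
#'
#' @return Character vector of supported conventions.
#' @export
discount_conventions <- function() {
  c("semiannual_midperiod", "annual_endperiod", "continuous")
}

#' Present value of a stream of life-years (or an annual cost stream)
#'
#' Computes the present value at model entry (t = 0) of one unit per year
#' accrued continuously from `t = delay` to `t = delay + length`, under an
#' annual discount rate and one of three accrual conventions:
#'
#' * `semiannual_midperiod` (default): accrual in 6-month slices, each slice
#'   of size `s` contributing `s * (1 + r)^(-t_mid)` with `t_mid` the slice
#'   midpoint in years; a fractional terminal slice is discounted at its own
#'   midpoint. This matches the model's 6-month step structure.
#' * `annual_endperiod`: 1-year slices discounted at slice end (the textbook
#'   annuity-immediate).
#' * `continuous`: the closed form
#'   `(1 + r)^(-delay) * (1 - (1 + r)^(-length)) / log(1 + r)`.
#'
#' All conventions return `length` exactly when `rate = 0`, and are monotone
#' decreasing in `delay` and in `rate`. Multiplying an annual cost by the
#' returned value prices the corresponding cost stream.
#'
#' @param length Years of accrual (vectorised, `>= 0`).
#' @param delay Years from model entry to the start of accrual (vectorised,
#'   `>= 0`).
#' @param rate Annual discount rate as a fraction (default 0.03).
#' @param convention One of [discount_conventions()].
#' @return Numeric vector of discounted years.
#'
#' @examples
#' discount_years(20, rate = 0.03)                  # ~15.1 discounted years
#' discount_years(10, rate = 0)                     # exactly 10
#' discount_years(10, delay = 2, rate = 0.03, convention = "continuous")
#' @export
discount_years <- function(length, delay = 0, rate = 0.03,
                           convention = discount_conventions()) {
  convention <- match.arg(convention)
  if (any(length < 0) || any(delay < 0)) {
    stop("length and delay must be non-negative", call. = FALSE)
  }
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  n <- max(base::length(length), base::length(delay))
  length <- rep_len(length, n)
  delay <- rep_len(delay, n)
  if (rate == 0) {
    return(length)
  }
  v <- 1 + rate
  switch(convention,
    continuous = v^(-delay) * (1 - v^(-length)) / log(v),
    semiannual_midperiod = midperiod_sum(length, delay, v, h = 0.5),
    annual_endperiod = endperiod_sum(length, delay, v, h = 1)
  )
}

# closed-form geometric sum over h-year slices discounted at slice midpoints
midperiod_sum <- function(length, delay, v, h) {
  nfull <- floor(length / h + 1e-12)
  frac <- pmax(length - nfull * h, 0)
  frac[frac < 1e-12] <- 0
  r <- v^(-h)
  full <- ifelse(nfull > 0,
                 h * v^(-(delay + h / 2)) * (1 - r^nfull) / (1 - r),
                 0)
  tail <- ifelse(frac > 0,
                 frac * v^(-(delay + nfull * h + frac / 2)),
                 0)
  full + tail
}

# h-year slices discounted at slice end
endperiod_sum <- function(length, delay, v, h) {
  nfull <- floor(length / h + 1e-12)
  frac <- pmax(length - nfull * h, 0)
  frac[frac < 1e-12] <- 0
  r <- v^(-h)
  full <- ifelse(nfull > 0,
                 h * v^(-delay) * r * (1 - r^nfull) / (1 - r),
                 0)
  tail <- ifelse(frac > 0,
                 frac * v^(-(delay + nfull * h + frac)),
                 0)
  full + tail
}

#' Point discount factor
#'
#' `(1 + rate)^(-t)`: the factor applied to a quantity realised at time `t`
#' years after model entry.
#'
#' @param t Time in years (vectorised, `>= 0`).
#' @inheritParams discount_years
#' @return Numeric vector of factors in (0, 1].
#' @export
discount_factor <- function(t, rate = 0.03) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  (1 + rate)^(-t)
}

#' Disability-weighted discounted life-years (the YLD mass of one life)
#'
#' Weights a discounted stream of life-years by disability: all years up to
#' the terminal AIDS period carry the HIV weight, and the final
#' `aids_years_before_death` years carry the AIDS weight. The difference in
#' this quantity between two scenarios is the (signed) YLD term of the DALY.
#'
#' @param length Total years lived from the start of the stream; must be at
#'   least `aids_years_before_death`.
#' @param delay Years from model entry to the start of the stream.
#' @param hiv_weight,aids_weight Disability weights in `[0, 1]`.
#' @param aids_years_before_death Length of the terminal AIDS period, years.
#' @inheritParams discount_years
#' @return Numeric vector of disability-weighted discounted years.
#'
#' @examples
#' # one HIV year then one terminal AIDS year, undiscounted:
#' disability_weighted_years(2, rate = 0) # 0.123 + 0.5
#' @export
disability_weighted_years <- function(length, delay = 0, rate = 0.03,
                                      convention = discount_conventions(),
                                      hiv_weight = 0.123, aids_weight = 0.5,
                                      aids_years_before_death = 1) {
  convention <- match.arg(convention)
  if (any(length < aids_years_before_death)) {
    stop("length must be at least aids_years_before_death", call. = FALSE)
  }
  pre <- discount_years(length - aids_years_before_death, delay, rate, convention)
  total <- discount_years(length, delay, rate, convention)
  hiv_weight * pre + aids_weight * (total - pre)
}
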