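# shared fixtures and independent oracles

base_params <- function(...) cea_parameters(...)

# brute-force waiting oracle: simulate measurement by measurement
wait_oracle <- function(baseline, decline, threshold = 250) {
  cd4 <- baseline
  k <- 0
  if (cd4 < threshold) {
    return(list(periods = 0, start_cd4 = cd4))
  }
  repeat {
    k <- k + 1
    cd4 <- cd4 - decline
    if (cd4 < threshold) {
      return(list(periods = k, start_cd4 = max(cd4, 0)))
    }
  }
}

# brute-force discounting oracle: direct summation over slices of width h,
# each discounted at its midpoint (independent of the closed-form code path)
discount_sum_oracle <- function(length, delay = 0, rate = 0.03, h = 0.5) {
  if (rate == 0) {
    return(length)
  }
  v <- 1 + rate
  t <- delay
  total <- 0
  remaining <- length
  while (remaining > 1e-12) {
    s <- min(h, remaining)
    total <- total + s * v^(-(t + s / 2))
    t <- t + s
    remaining <- remaining - s
  }
  total
}

# closed-form continuous annuity
annuity_continuous <- function(length, delay = 0, rate = 0.03) {
  if (rate == 0) {
    return(length)
  }
  v <- 1 + rate
  v^(-delay) * (1 - v^(-length)) / log(v)
}
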