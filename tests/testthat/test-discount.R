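test_that("zero rate returns the undiscounted length under every convention", {
  lengths <- c(0, 0.25, 1, 7.3, 30)
  delays <- c(0, 0.5, 2)
  for (conv in discount_conventions()) {
    for (d in delays) {
      expect_equal(discount_years(lengths, d, rate = 0, convention = conv),
                   lengths)
    }
  }
})

test_that("semiannual mid-period closed form matches direct slice summation", {
  cases <- expand.grid(length = c(0.3, 1, 15.51, 20.93, 28.7),
                       delay = c(0, 0.5, 1.5), rate = c(0.03, 0.06))
  for (i in seq_len(nrow(cases))) {
    expect_equal(
      discount_years(cases$length[i], cases$delay[i], cases$rate[i],
                     "semiannual_midperiod"),
      discount_sum_oracle(cases$length[i], cases$delay[i], cases$rate[i],
                          h = 0.5),
      tolerance = 1e-12
    )
  }
})

test_that("mid-period summation converges to the continuous annuity as slices shrink", {
  # closed-form oracle for a 1-year stream at 3%
  expected <- (1 - exp(-log(1.03))) / log(1.03)
  expect_equal(annuity_continuous(1), expected, tolerance = 1e-12)
  expect_equal(discount_years(1, rate = 0.03, convention = "continuous"),
               expected, tolerance = 1e-12)
  for (L in c(1, 10, 25)) {
    steps <- vapply(c(0.5, 0.1, 0.01),
                    function(h) discount_sum_oracle(L, 0, 0.03, h = h),
                    numeric(1))
    errs <- abs(steps - annuity_continuous(L))
    expect_true(all(diff(errs) < 0))  # error shrinks monotonically
    expect_lt(errs[3], 1e-5 * L)
  }
})

test_that("mid-period and continuous agree within 1% for streams up to 30 years at 3%", {
  for (L in seq(0.5, 30, by = 0.5)) {
    mid <- discount_years(L, rate = 0.03, convention = "semiannual_midperiod")
    cont <- discount_years(L, rate = 0.03, convention = "continuous")
    expect_lt(abs(mid - cont) / cont, 0.01)
  }
})

test_that("discounted years are monotone decreasing in rate and in delay", {
  for (conv in discount_conventions()) {
    r <- vapply(c(0, 0.03, 0.06),
                function(r) discount_years(20, 0, r, conv), numeric(1))
    expect_true(all(diff(r) < 0))
    d <- vapply(c(0, 0.5, 1, 2),
                function(d) discount_years(20, d, 0.03, conv), numeric(1))
    expect_true(all(diff(d) < 0))
  }
})

test_that("delay factors out for time-separable kernels", {
  for (d in c(0.5, 1, 2.5)) {
    expect_equal(
      discount_years(17, d, 0.03, "continuous"),
      1.03^(-d) * discount_years(17, 0, 0.03, "continuous")
    )
    # mid-period is separable when the delay is a multiple of the period
    expect_equal(
      discount_years(17, d, 0.03, "semiannual_midperiod"),
      1.03^(-d) * discount_years(17, 0, 0.03, "semiannual_midperiod")
    )
  }
})

test_that("negative arguments are domain errors", {
  expect_error(discount_years(-1), "non-negative")
  expect_error(discount_years(1, delay = -0.5), "non-negative")
  expect_error(discount_factor(-1), "non-negative")
})

test_that("disability-weighted years weight the terminal AIDS period at its own weight", {
  # entire life is the terminal AIDS year
  expect_equal(disability_weighted_years(1, rate = 0), 0.5)
  # one HIV year plus one terminal AIDS year, undiscounted
  expect_equal(disability_weighted_years(2, rate = 0), 0.123 + 0.5)
  # discounted value is bounded by the discounted stream times the max weight
  for (conv in discount_conventions()) {
    dwy <- disability_weighted_years(15.51, rate = 0.03, convention = conv)
    total <- discount_years(15.51, rate = 0.03, convention = conv)
    expect_gt(dwy, 0.123 * total)
    expect_lt(dwy, 0.5 * total)
  }
  expect_error(disability_weighted_years(0.5), "aids_years_before_death")
})
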