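test_that("the fitted decline distribution matches the quantities it can match", {
  fit <- fit_decline_distribution(45.75, 30.65, 62.35)
  # median is matched to machine precision by construction
  expect_equal(qlnorm(0.5, fit$meanlog, fit$sdlog), 45.75, tolerance = 1e-12)
  # the interquartile *ratio* is matched exactly ...
  q <- qlnorm(c(0.25, 0.75), fit$meanlog, fit$sdlog)
  expect_equal(q[2] / q[1], 62.35 / 30.65, tolerance = 1e-12)
  # ... while the individual quartiles are approximate (the published
  # quartiles are not log-symmetric about the median), within 5%
  expect_equal(q[1], 30.65, tolerance = 0.05)
  expect_equal(q[2], 62.35, tolerance = 0.05)
  expect_error(fit_decline_distribution(1, 1, 1), "q25 < median < q75")
  expect_error(fit_decline_distribution(10, 20, 30), "q25 < median < q75")
})

test_that("cohorts are reproducible and carry the assumed population structure", {
  p <- base_params()
  c1 <- sample_cohort(5000, p, seed = 42)
  c2 <- sample_cohort(5000, p, seed = 42)
  expect_identical(c1, c2)
  expect_false(identical(c1, sample_cohort(5000, p, seed = 43)))
  expect_error(sample_cohort(10, p), "seed")

  big <- sample_cohort(10000, p, seed = 7)
  expect_true(all(big$baseline_cd4 >= 250 & big$baseline_cd4 <= 350))
  expect_equal(mean(big$baseline_cd4), 300, tolerance = 1 / 300)
  expect_equal(median(big$decline_per_period), 45.75, tolerance = 1 / 45.75)
  expect_true(all(big$decline_per_period > 0))

  one <- sample_cohort(1, p, seed = 1)
  expect_equal(nrow(one), 1)

  tp <- sample_cohort(4000, p, seed = 9, decline_distribution = "three_point")
  expect_setequal(unique(tp$decline_per_period), c(30.65, 45.75, 62.35))
})

test_that("a degenerate cohort reproduces the deterministic mean row exactly", {
  p <- base_params()
  bins <- cd4_bins(p)
  cohort <- tibble::tibble(baseline_cd4 = bins$midpoint,
                           decline_per_period = 45.75)
  ms <- microsimulate(cohort, p)
  det <- cea_summary(evaluate_cohort(p), p)
  det_mean <- det$rows[det$rows$row == "mean", ]
  s <- ms$summary
  expect_equal(s$mean[s$quantity == "daly_averted"], det_mean$daly_averted,
               tolerance = 1e-12)
  expect_equal(s$mean[s$quantity == "incremental_cost"],
               det_mean$incremental_cost, tolerance = 1e-12)
  expect_equal(s$mean[s$quantity == "yll"], det_mean$yll, tolerance = 1e-12)
  expect_equal(ms$icer, det_mean$icer, tolerance = 1e-12)
})

test_that("cohort means converge near the deterministic model under heterogeneity", {
  p <- base_params()
  ms <- microsimulate(sample_cohort(20000, p, seed = 11), p)
  det <- cea_summary(evaluate_cohort(p), p)
  det_daly <- det$rows$daly_averted[det$rows$row == "mean"]
  g <- glance(ms)
  # continuous baselines and decline heterogeneity shift the mean modestly
  expect_lt(abs(g$daly_averted - det_daly), 0.3)
  expect_gt(g$daly_averted, 0)
  expect_lt(g$daly_averted_se, 0.02)
})

test_that("Monte-Carlo standard errors scale as one over root n", {
  p <- base_params()
  ns <- c(1000, 4000, 16000)
  ses <- vapply(ns, function(n) {
    glance(microsimulate(sample_cohort(n, p, seed = 5), p))$daly_averted_se
  }, numeric(1))
  # quadrupling n should halve the se, within 25%
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.25)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.25)
})

test_that("uniformly slower decline lengthens the cohort's waiting time", {
  p <- base_params()
  cohort <- sample_cohort(2000, p, seed = 3)
  slow <- dplyr::mutate(cohort, decline_per_period = 30.65)
  base <- dplyr::mutate(cohort, decline_per_period = 45.75)
  mw_slow <- mean(microsimulate(slow, p)$patients$b_wait_years)
  mw_base <- mean(microsimulate(base, p)$patients$b_wait_years)
  expect_gte(mw_slow, mw_base)
})
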