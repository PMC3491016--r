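test_that("inpatient day totals combine OI and non-OI admissions per cell", {
  p <- base_params()
  expect_equal(inpatient_days_per_year("cd4_201_350", FALSE, p), 10.8 + 3.0)
  expect_equal(inpatient_days_per_year("cd4_gt_350", TRUE, p), 0.37 + 0.14)
  expect_error(inpatient_days_per_year("cd4_0_200", TRUE, p), "unknown CD4 stratum")

  zero <- cea_parameters(inpatient = list(rates = {
    r <- p$inpatient$rates
    r$days_per_year <- 0
    r
  }))
  expect_equal(inpatient_days_per_year("cd4_201_350", FALSE, zero), 0)
})

test_that("lifetime treatment cost prices the waiting and on-treatment streams", {
  p <- base_params()
  expect_equal(lifetime_treatment_cost(0, 0, p)$treatment_total, 0)
  # at 0% discount the accounting is exact: 84.76*wait + 305.84*years
  p0 <- cea_parameters(discount = list(annual_rate = 0))
  tc <- lifetime_treatment_cost(1.5, 20, p0)
  expect_equal(tc$waiting_monitoring, 84.76 * 1.5)
  expect_equal(tc$cart_and_monitoring, 305.84 * 20)
  expect_equal(tc$treatment_total, 84.76 * 1.5 + 305.84 * 20)
  expect_error(lifetime_treatment_cost(-1, 5, p), "non-negative")
})

test_that("hospitalization cost matches hand arithmetic on degenerate inputs", {
  # one year off cART in the 201-350 stratum, undiscounted: 13.8 d/yr * $31.48
  p1 <- cea_parameters(hospitalization_horizon = 1,
                       discount = list(annual_rate = 0))
  traj <- tibble::tibble(t_start = c(0, 0.5), on_cart = FALSE,
                         cd4 = 300, stratum = "cd4_201_350")
  expect_equal(hospitalization_cost(traj, p1), 13.8 * 31.48)

  # all-zero rates cost nothing
  pz <- base_params()
  pz$inpatient$rates$days_per_year <- 0
  traj4 <- scenario_trajectory(305, 1, 213.5, 45.75, pz)
  expect_equal(hospitalization_cost(traj4, pz), 0)

  # a trajectory shorter than the horizon is an error
  expect_error(hospitalization_cost(traj, base_params()), "horizon")
})

test_that("the state trajectory switches from declining to reconstituting at initiation", {
  p <- base_params()
  tr <- scenario_trajectory(305, 1, 213.5, 45.75, p)
  expect_equal(tr$on_cart, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(tr$cd4, c(305, 305 - 45.75, 213.5, 213.5 + 57))
  expect_true(all(tr$stratum == "cd4_201_350"))
  # immediate initiation crosses into the >350 stratum via reconstitution
  tra <- scenario_trajectory(345, 0, 345, 45.75, p)
  expect_equal(tra$stratum, c("cd4_201_350", rep("cd4_gt_350", 3)))
})

test_that("scenario cost components are linear in unit costs", {
  p <- base_params()
  doubled <- cea_parameters(costs = list(
    cart_drug_annual = 2 * 192.44,
    cart_maintenance_annual = 2 * 113.40,
    waiting_components = lapply(p$costs$waiting_components, `*`, 2),
    cost_per_inpatient_day = 2 * 31.48
  ))
  c1 <- scenario_cost(305, 1, 213.5, 15.3, 45.75, p)
  c2 <- scenario_cost(305, 1, 213.5, 15.3, 45.75, doubled)
  expect_equal(c2$waiting_monitoring, 2 * c1$waiting_monitoring)
  expect_equal(c2$cart_and_monitoring, 2 * c1$cart_and_monitoring)
  expect_equal(c2$hospitalization, 2 * c1$hospitalization)
  expect_equal(c2$net, 2 * c1$net)
  # breakdown adds up
  expect_equal(c1$net,
               c1$waiting_monitoring + c1$cart_and_monitoring + c1$hospitalization)
})

test_that("hospitalization cost is monotone in rates and bed-day cost, and higher while waiting", {
  p <- base_params()
  co <- evaluate_cohort(p)
  # off-cART rates dominate: deferred arm hospitalizes more in every bin
  expect_true(all(co$b_cost_hospitalization > co$a_cost_hospitalization))

  scaled <- perturb_parameters(p, "inpatient_days_scale", 1.5)
  co_s <- evaluate_cohort(scaled)
  expect_true(all(co_s$a_cost_hospitalization > co$a_cost_hospitalization))
  expect_true(all(co_s$b_cost_hospitalization > co$b_cost_hospitalization))

  dearer <- perturb_parameters(p, "cost_per_day", 47.22)
  co_d <- evaluate_cohort(dearer)
  expect_true(all(co_d$b_cost_hospitalization > co$b_cost_hospitalization))
})
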