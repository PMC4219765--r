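test_that("dynamic intake follows relative mass with exponent gamma", {
  ip <- intake_params(0.3, 3506.32, 99.52)
  # fixed point at the initial mass
  expect_equal(intake_update(ip, 99.52), 3506.32)
  # gamma = 0 decouples intake from mass
  ip0 <- intake_params(0, 2500, 80)
  expect_equal(intake_update(ip0, c(40, 80, 160)), rep(2500, 3))
  # worked value: the fig-3 male down at 90 kg
  expect_equal(intake_update(ip, 90), 3402.132, tolerance = 1e-4)
  # monotone in mass for gamma > 0
  masses <- seq(60, 140, by = 5)
  expect_true(all(diff(intake_update(ip, masses)) > 0))
  expect_error(intake_update(ip, -5), "> 0")
  expect_error(intake_params(1.2, 2500, 80), "\\[0, 1\\]")
})

test_that("basal expenditure uses the sex/age bracket coefficients", {
  ep <- expenditure_params()
  expect_equal(basal_expenditure("male", 38.44, 99.52, ep),
               11.472 * 99.52 + 873.1)
  expect_equal(basal_expenditure("female", 34.54, 50.01, ep),
               8.126 * 50.01 + 845.6)
  expect_equal(basal_expenditure("male", 20.26, 74.69, ep),
               15.057 * 74.69 + 692.2)
  # strictly increasing in mass within a bracket
  w <- seq(45, 120, by = 5)
  b <- vapply(w, function(x) basal_expenditure("female", 25, x, ep), 1)
  expect_true(all(diff(b) > 0))
  # unsupported bracket errors and names the supported ones
  expect_error(basal_expenditure("male", 12, 40, ep), "supported brackets")
  expect_error(basal_expenditure("female", 75, 60, ep), "supported brackets")
})

test_that("thermogenesis is the configured linear fraction of intake", {
  expect_equal(thermogenesis(0), 0)
  expect_equal(thermogenesis(2821.48, 0.10), 282.148)
  a <- 1234.5; b <- 678.9
  expect_equal(thermogenesis(a + b), thermogenesis(a) + thermogenesis(b))
  expect_error(thermogenesis(-10), ">= 0")
})

test_that("activity calibration reproduces the initial expenditure exactly", {
  for (preset in c("fig1", "fig2", "fig3", "fig4")) {
    prof <- fig(preset)
    ep <- calibrate_activity(prof, expenditure_params())
    expect_equal(
      total_expenditure(prof$sex, prof$age_years, prof$mass0_kg,
                        prof$intake0_kcal, ep),
      prof$expend0_kcal, tolerance = 1e-9
    )
  }
  # the fig-3 male's per-kg activity cost
  ep3 <- calibrate_activity(fig("fig3"), expenditure_params())
  expect_equal(ep3$activity_per_kg, 11.67689, tolerance = 1e-4)
  # composed expenditure off the initial point
  expect_equal(total_expenditure("male", 38.44, 90, 3402.1, ep3),
               3296.711, tolerance = 1e-3)
  # sedentary limit: E0 = B0 + beta * I0 gives zero activity
  prof <- individual_profile(
    "sed", "male", 40, 1.75, 80, 20,
    intake0_kcal = 2000,
    expend0_kcal = 11.472 * 80 + 873.1 + 0.1 * 2000, gamma = 0.3,
    max_gap_kcal = Inf
  )
  expect_equal(calibrate_activity(prof)$activity_per_kg, 0)
  # inconsistent initial conditions are refused
  bad <- individual_profile("bad", "male", 40, 1.75, 80, 20,
                            intake0_kcal = 2000, expend0_kcal = 1000,
                            gamma = 0.3, max_gap_kcal = Inf)
  expect_error(calibrate_activity(bad), "negative activity")
})

test_that("total expenditure is strictly increasing in mass at fixed intake", {
  ep <- calibrate_activity(fig("fig3"), expenditure_params())
  w <- seq(70, 120, by = 2)
  e <- vapply(w, function(x) total_expenditure("male", 38.44, x, 3400, ep), 1)
  expect_true(all(diff(e) > 0))
})

test_that("deterministic runs land on the analytic balance point for every gamma", {
  prof <- fig("fig3")
  for (g in seq(0.1, 0.5, by = 0.1)) {
    m_star <- equilibrium_mass(prof, gamma = g)
    traj <- simulate_individual(prof, horizon_days = 6000, gamma = g)
    n <- nrow(traj)
    expect_lt(abs(traj$intake_kcal[n] - traj$expend_kcal[n]), 0.5)
    expect_equal(traj$mass_kg[n], m_star, tolerance = 1e-3)
  }
})

test_that("weight change follows the sign of the initial energy gap", {
  t3 <- simulate_individual(fig("fig3"), horizon_days = 1500)
  expect_lt(t3$mass_kg[nrow(t3)], 99.52)
  t4 <- simulate_individual(fig("fig4"), horizon_days = 1500)
  expect_gt(t4$mass_kg[nrow(t4)], 50.01)
})
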