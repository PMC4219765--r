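test_that("Forbes partition fraction behaves like C/(C+F)", {
  m <- default_model()
  C <- m$forbes_C_kg
  expect_equal(C, 10.4 * 1800 / 9400)
  # symmetry point and vanishing limit
  expect_equal(forbes_p(C, m), 0.5)
  expect_lt(forbes_p(200 * C, m), 0.01)
  # worked value for the fig-1 male's initial fat mass
  expect_equal(forbes_p(12.96, m), 0.1331967, tolerance = 1e-6)
  # in (0,1) and strictly decreasing over a wide fat-mass grid
  f <- seq(0.01, 150, length.out = 500)
  p <- forbes_p(f, m)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) < 0))
  expect_error(forbes_p(0, m), "must be > 0")
  expect_error(forbes_p(-3, m), "must be > 0")
})

test_that("first-difference ratio returns dL/dM unclamped, with fallback", {
  expect_equal(hall_p(0, -0.5, fallback_p = 0.9), 0)
  expect_equal(hall_p(-0.5, -0.5, fallback_p = 0.9), 1)
  expect_equal(hall_p(-0.2, -0.5, fallback_p = 0.9), 0.4)
  # out-of-range ratios must survive untouched
  expect_equal(hall_p(-0.7, -0.5, fallback_p = 0.9), 1.4)
  expect_equal(hall_p(0.3, -0.5, fallback_p = 0.9), -0.6)
  # degenerate mass change falls back
  expect_equal(hall_p(1e-12, 1e-12, fallback_p = 0.37), 0.37)
})

test_that("a daily partition step moves the compartments per the energy split", {
  st <- body_state(12.96, 59.09, height_m = 1.88)
  m <- default_model()
  # zero imbalance leaves the state untouched
  same <- partition_step(st, 0, forbes_p(st$fat_kg, m), m)
  expect_equal(same$fat_kg, st$fat_kg)
  expect_equal(same$lean_kg, st$lean_kg)
  # the fig-1 male's first day of deficit
  new <- partition_step(st, -427.27, 0.1332, m)
  expect_equal(new$lean_kg - st$lean_kg, -0.0316180, tolerance = 1e-5)
  expect_equal(new$fat_kg - st$fat_kg, -0.0393997, tolerance = 1e-5)
  expect_false(attr(new, "clamped"))
  expect_error(partition_step(st, NaN, 0.5, m), "finite")
  expect_error(partition_step(st, Inf, 0.5, m), "finite")
})

test_that("energy conservation holds to 1e-9 over 1e5 random steps, both bases", {
  s <- random_steps(1e5)
  dens <- energy_densities()
  for (basis in c("energy", "mass")) {
    d <- partition_deltas(s$imb, s$p, dens, basis = basis)
    recovered <- dens$rho_F * d$dF + dens$rho_L * d$dL
    expect_lt(max(abs(recovered - s$imb) / pmax(abs(s$imb), 1)), 1e-9)
  }
})

test_that("the mass-share basis realizes p as the lean fraction of dM", {
  dens <- energy_densities()
  d <- partition_deltas(-500, 0.445, dens, basis = "mass")
  expect_equal(d$dL / (d$dL + d$dF), 0.445)
  # near-singular effective density is refused rather than blowing up
  p_sing <- dens$rho_F / (dens$rho_F - dens$rho_L)
  expect_error(partition_deltas(-500, p_sing, dens, basis = "mass"),
               "degenerate")
})

test_that("Forbes dynamics keep fat nonnegative under sustained deficit", {
  # fixed large deficit, ignoring the intake/expenditure laws: pure partition
  m <- default_model()
  st <- body_state(5, 55)
  clamped <- FALSE
  for (i in 1:4000) {
    st <- partition_step(st, -800, forbes_p(max(st$fat_kg, 1e-12), m), m)
    expect_gte(st$fat_kg, 0)
    if (attr(st, "clamped")) { clamped <- TRUE; break }
  }
  # a deficit this brutal ends in the clamped terminal state
  expect_true(clamped)
})

test_that("daily Euler agrees with a 10x finer step within 1% over a year", {
  prof <- fig("fig3")
  coarse <- simulate_individual(prof, horizon_days = 365)
  ep <- calibrate_activity(prof, expenditure_params())
  ip <- intake_params(prof$gamma, prof$intake0_kcal, prof$mass0_kg)
  pm <- default_model()
  st <- body_state(prof$fat0_kg, prof$lean0_kg, prof$height_m)
  for (k in seq_len(3650)) {
    I <- intake_update(ip, st$mass_kg)
    E <- total_expenditure(prof$sex, prof$age_years, st$mass_kg, I, ep)
    st <- partition_step(st, I - E, forbes_p(st$fat_kg, pm), pm, dt = 0.1)
  }
  expect_equal(coarse$mass_kg[nrow(coarse)], st$mass_kg, tolerance = 0.01)
})

test_that("constructors enforce their physical invariants", {
  expect_error(energy_densities(rho_F = 1000, rho_L = 1800), "rho_F > rho_L")
  expect_error(energy_densities(rho_L = -1), "rho_F > rho_L")
  expect_error(partition_model(forbes_C_kg = 0), "must be > 0")
  expect_error(body_state(10, -1), "lean_kg")
  # Hall runs may carry negative fat: the state constructor records it
  st <- body_state(-0.5, 50)
  expect_equal(st$mass_kg, 49.5)
})
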