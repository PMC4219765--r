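test_that("a balanced individual does not move", {
  prof <- individual_profile(
    "flat", "male", 40, 1.80, 81, 20,
    intake0_kcal = 2800, expend0_kcal = 2800, gamma = 0.3
  )
  traj <- simulate_individual(prof, horizon_days = 30)
  expect_equal(traj$mass_kg, rep(81, 31))
  expect_equal(traj$intake_kcal[-1], rep(2800, 30))
  expect_equal(traj$expend_kcal[-1], rep(2800, 30))
})

test_that("the first record equals the initial conditions and mass closes", {
  traj <- simulate_individual(fig("fig3"), horizon_days = 200)
  expect_equal(traj$day[1], 0)
  expect_equal(traj$fat_kg[1], fig("fig3")$fat0_kg)
  expect_equal(traj$lean_kg[1], fig("fig3")$lean0_kg)
  expect_equal(traj$intake_kcal[1], 3506.32)
  expect_equal(traj$expend_kcal[1], 3527.51)
  expect_lt(max(abs(traj$fat_kg + traj$lean_kg - traj$mass_kg)), 1e-9)
  # day 1 reproduces the initial intake/expenditure (calibration identity)
  expect_equal(traj$intake_kcal[2], 3506.32, tolerance = 1e-9)
  expect_equal(traj$expend_kcal[2], 3527.51, tolerance = 1e-6)
})

test_that("Forbes protects the fat compartment; the Hall rule does not", {
  f <- simulate_individual(fig("fig1"), horizon_days = 2500, p_kind = "forbes")
  expect_gte(min(f$fat_kg), 0)
  expect_false(any(f$negative_fat))
  h <- simulate_individual(fig("fig1"), horizon_days = 2500, p_kind = "hall")
  expect_lt(min(h$fat_kg), 0)
  expect_true(any(h$negative_fat))
  # the pathology is recorded, not hidden: run continues to the horizon
  expect_equal(nrow(h), 2501)
  # total-mass paths of the two rules stay close even as composition diverges
  expect_lt(max(abs(f$mass_kg - h$mass_kg)) / f$mass_kg[1], 0.05)
})

test_that("gaining weight, the Hall rule grows lean faster than Forbes does", {
  f <- simulate_individual(fig("fig2"), horizon_days = 2000, p_kind = "forbes")
  h <- simulate_individual(fig("fig2"), horizon_days = 2000, p_kind = "hall")
  dl_f <- f$lean_kg[nrow(f)] - f$lean_kg[1]
  dl_h <- h$lean_kg[nrow(h)] - h$lean_kg[1]
  expect_gt(dl_h, dl_f)
})

test_that("a clamped Forbes run stops with a flagged terminal record", {
  # a total fast: intake pinned at zero can never balance the basal floor,
  # so the run must end at the clamped emaciation point
  prof <- individual_profile(
    "fast", "male", 40, 1.80, 60, 3.5,
    intake0_kcal = 0, expend0_kcal = 2500, gamma = 0, max_gap_kcal = Inf
  )
  traj <- simulate_individual(prof, horizon_days = 4000)
  expect_equal(attr(traj, "status"), "clamped")
  expect_true(traj$clamped[nrow(traj)])
  expect_lt(nrow(traj), 4001)
  expect_gte(min(traj$fat_kg), 0)
})

test_that("stochastic runs are reproducible from their seed", {
  cfg <- run_config(fig("fig3"), horizon_days = 400, gamma = 0.3,
                    social = social_params("random"), seed = 123)
  a <- simulate_individual(cfg)
  b <- simulate_individual(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_individual(run_config(fig("fig3"), horizon_days = 400,
                                      gamma = 0.3,
                                      social = social_params("random"),
                                      seed = 124))
  expect_false(identical(a$mass_kg, c$mass_kg))
})

test_that("the cumulative energy budget closes on noisy and noiseless runs", {
  quiet <- simulate_individual(fig("fig4"), horizon_days = 1000)
  expect_lt(audit_conservation(quiet), 1e-8)
  noisy <- simulate_individual(fig("fig4"), horizon_days = 1000, gamma = 0.3,
                               social = social_params("random"), seed = 21)
  expect_lt(audit_conservation(noisy), 1e-8)
  hall <- simulate_individual(fig("fig1"), horizon_days = 1000,
                              p_kind = "hall")
  expect_lt(audit_conservation(hall), 1e-8)
})

test_that("the simulated equilibrium matches the root of the balance equation", {
  for (preset in c("fig3", "fig4")) {
    prof <- fig(preset)
    m_star <- equilibrium_mass(prof)
    traj <- simulate_individual(prof, horizon_days = 4000)
    expect_equal(traj$mass_kg[nrow(traj)], m_star, tolerance = 1e-4)
  }
})

test_that("gamma is recoverable from a clean trajectory by grid least squares", {
  prof <- fig("fig3")
  for (g_true in c(0.2, 0.35)) {
    obs <- simulate_individual(prof, horizon_days = 800, gamma = g_true)
    est <- estimate_gamma(obs, prof)
    expect_lt(abs(as.numeric(est) - g_true), 0.05 + 1e-12)
    sse <- attr(est, "sse")
    expect_equal(names(which.min(sse)), format(g_true))
  }
})

test_that("trajectories round-trip to CSV with a JSON sidecar", {
  traj <- simulate_individual(fig("fig4"), horizon_days = 50, gamma = 0.3,
                              social = social_params("random"), seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- utils::read.csv(path)
  expect_equal(back$mass_kg, traj$mass_kg, tolerance = 1e-8)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$seed, 9)
  expect_equal(meta$p_kind, "forbes")
  expect_equal(meta$profile$mass0_kg, 50.01)
  expect_equal(meta$social$case, "random")
})

test_that("core-module failures surface with a usable message", {
  prof <- individual_profile("old", "female", 59.9, 1.6, 60, 18,
                             intake0_kcal = 2000, expend0_kcal = 2100,
                             gamma = 0.3)
  ok <- simulate_individual(prof, horizon_days = 5)  # 59.9 is in-bracket
  expect_equal(nrow(ok), 6)
  prof$age_years <- 70
  expect_error(simulate_individual(prof, horizon_days = 5),
               "supported brackets")
})
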