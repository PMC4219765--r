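#' Assemble a simulation run configuration
#'
#' @param profile An [individual_profile()] (e.g. from
#'   [profile_from_caption()] or [as_profile()]).
#' @param horizon_days Number of daily steps (>= 1). The default 1500 days is
#'   long enough for the example individuals to approach their equilibrium.
#' @param p_kind Partition rule, `"forbes"` or `"hall"`.
#' @param densities [energy_densities()] of the two compartments.
#' @param forbes_C_kg Forbes constant; default `10.4 * rho_L / rho_F`.
#' @param expenditure [expenditure_params()]; calibrated automatically against
#'   the profile's initial conditions.
#' @param social [social_params()] for the daily perturbation.
#' @param gamma Optional override of the profile's intake responsiveness.
#' @param seed Optional integer seed (needed only for stochastic social
#'   cases; recorded in the trajectory metadata either way).
#' @return An object of class `run_config`.
#' @export
run_config <- function(profile, horizon_days = 1500,
                       p_kind = c("forbes", "hall"),
                       densities = energy_densities(),
                       forbes_C_kg = NULL,
                       expenditure = expenditure_params(),
                       social = social_params("off"),
                       gamma = NULL, seed = NULL) {
  stopifnot(inherits(profile, "individual_profile"))
  stopifnot_scalar(horizon_days, "horizon_days")
  if (horizon_days < 1) stop("`horizon_days` must be >= 1", call. = FALSE)
  p_kind <- match.arg(p_kind)
  stopifnot(inherits(social, "social_params"))
  if (!is.null(gamma)) {
    stopifnot_scalar(gamma, "gamma")
    profile$gamma <- gamma
  }
  model <- partition_model(
    densities = densities,
    forbes_C_kg = forbes_C_kg %||% (10.4 * densities$rho_L / densities$rho_F),
    p_kind = p_kind
  )
  structure(
    list(
      profile = profile, horizon_days = as.integer(horizon_days),
      model = model, expenditure = expenditure, social = social, seed = seed
    ),
    class = "run_config"
  )
}

#' Simulate one individual's daily body-mass trajectory
#'
#' Advances the two-compartment energy-balance model with a one-day explicit
#' Euler step. Each day, in order: the social term is drawn (if enabled);
#' intake follows the current mass through the responsiveness law; total
#' expenditure is decomposed into basal + thermogenesis + activity; the
#' effective imbalance (including the social term) is split between the fat
#' and lean compartments by the configured partition rule.
#'
#' Under the Forbes rule a step that would empty a compartment clamps it at
#' zero, flags the record and stops the run; under the Hall rule negative fat
#' mass is recorded and flagged but the run continues.
#'
#' @param config A [run_config()] (an [individual_profile()] is accepted and
#'   wrapped with default settings).
#' @param ... Passed to [run_config()] when `config` is a profile.
#' @return A data frame of class `trajectory` with one row per day (day 0 =
#'   initial conditions) and columns `day, fat_kg, lean_kg, mass_kg,
#'   intake_kcal, expend_kcal, social_kcal, clamped, negative_fat`.
#'   Attributes: `profile`, `config`, `seed`, `status` (`"ok"` or
#'   `"clamped"`).
#' @export
#' @examples
#' traj <- simulate_individual(profile_from_caption("fig3"),
#'                             horizon_days = 365)
#' tail(traj$mass_kg, 1)
simulate_individual <- function(config, ...) {
  if (inherits(config, "individual_profile")) {
    config <- run_config(config, ...)
  }
  stopifnot(inherits(config, "run_config"))
  prof <- config$profile
  model <- config$model
  dens <- model$densities
  ip <- intake_params(prof$gamma, prof$intake0_kcal, prof$mass0_kg)
  ep <- calibrate_activity(prof, config$expenditure)
  n <- config$horizon_days

  fat <- lean <- intake <- expend <- social <- numeric(n + 1L)
  neg <- clamp <- logical(n + 1L)
  fat[1] <- prof$fat0_kg
  lean[1] <- prof$lean0_kg
  intake[1] <- prof$intake0_kcal
  expend[1] <- prof$expend0_kcal
  status <- "ok"
  last <- n + 1L

  with_seed(config$seed, {
    prev_dL <- prev_dM <- 0
    state <- body_state(fat[1], lean[1], prof$height_m)
    for (t in seq_len(n)) {
      step <- tryCatch({
        s <- if (config$social$case == "off") 0 else social_term(config$social)
        m <- state$mass_kg
        I <- intake_update(ip, m)
        E <- total_expenditure(prof$sex, prof$age_years, m, I, ep)
        imb <- perturbed_balance(I, E, s)
        if (model$p_kind == "forbes") {
          p <- forbes_p(state$fat_kg, model)
          basis <- "energy"
        } else if (t == 1L || abs(prev_dM) < 1e-9) {
          # (re)seed the first-difference recursion with a Forbes-consistent
          # step; max() guards the Forbes relation once fat has gone negative
          p <- forbes_p(max(state$fat_kg, 1e-6), model)
          basis <- "energy"
        } else {
          p <- hall_p(prev_dL, prev_dM,
                      fallback_p = forbes_p(max(state$fat_kg, 1e-6), model))
          basis <- "mass"
        }
        new <- partition_step(state, imb, p, model, basis = basis)
        list(new = new, s = s, I = I, E = E)
      }, error = function(e) {
        stop(sprintf("day %d: %s", t, conditionMessage(e)), call. = FALSE)
      })
      new <- step$new
      prev_dL <- new$lean_kg - state$lean_kg
      prev_dM <- new$mass_kg - state$mass_kg
      state <- new
      i <- t + 1L
      fat[i] <- state$fat_kg
      lean[i] <- state$lean_kg
      intake[i] <- step$I
      expend[i] <- step$E
      social[i] <- step$s
      neg[i] <- attr(state, "negative_fat")
      clamp[i] <- attr(state, "clamped")
      if (clamp[i]) {
        status <- "clamped"
        last <- i
        break
      }
    }
  })

  idx <- seq_len(last)
  out <- data.frame(
    day = idx - 1L, fat_kg = fat[idx], lean_kg = lean[idx],
    mass_kg = fat[idx] + lean[idx],
    intake_kcal = intake[idx], expend_kcal = expend[idx],
    social_kcal = social[idx], clamped = clamp[idx], negative_fat = neg[idx]
  )
  class(out) <- c("trajectory", "data.frame")
  attr(out, "profile") <- prof
  attr(out, "config") <- config
  attr(out, "seed") <- config$seed
  attr(out, "status") <- status
  out
}

#' @export
print.trajectory <- function(x, ...) {
  prof <- attr(x, "profile")
  nlast <- nrow(x)
  cat(sprintf(
    paste0("<trajectory> %s (%s), %d days, status %s\n",
           "  mass %.2f -> %.2f kg; final |I - E| = %.3f kcal/day\n"),
    as.character(prof$id), attr(x, "config")$model$p_kind, nlast - 1L,
    attr(x, "status"), x$mass_kg[1], x$mass_kg[nlast],
    abs(x$intake_kcal[nlast] - x$expend_kcal[nlast])
  ))
  invisible(x)
}

#' Plot a trajectory
#'
#' Base-graphics convenience: mass, intake and expenditure against time.
#'
#' @param x A `trajectory`.
#' @param y Ignored.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.trajectory <- function(x, y, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$day, x$mass_kg, type = "l", xlab = "day",
                 ylab = "mass [kg]", ...)
  graphics::plot(x$day, x$intake_kcal, type = "l", col = "forestgreen",
                 xlab = "day", ylab = "kcal/day",
                 ylim = range(c(x$intake_kcal, x$expend_kcal)))
  graphics::lines(x$day, x$expend_kcal, col = "firebrick")
  graphics::legend("topright", c("intake", "expenditure"), lty = 1,
                   col = c("forestgreen", "firebrick"), bty = "n")
  invisible(x)
}

#' Analytic equilibrium mass
#'
#' Solves the deterministic balance condition
#' `I0 * (m/m0)^gamma * (1 - beta) - B(m) - delta * m + social_const = 0`
#' by root finding -- an independent check of where the daily-step simulation
#' must converge in the absence of noise.
#'
#' @param profile An [individual_profile()].
#' @param expenditure [expenditure_params()]; calibrated internally.
#' @param gamma Optional override of the profile's `gamma`.
#' @param social_const Constant social term added to the balance, kcal/day.
#' @return Equilibrium mass, kg. The balance function can have several roots
#'   for large `gamma`; the one approached from the initial mass is returned,
#'   found by walking from `m0` in the direction of the initial imbalance
#'   until the balance changes sign.
#' @export
#' @examples
#' equilibrium_mass(profile_from_caption("fig4"))
equilibrium_mass <- function(profile, expenditure = expenditure_params(),
                             gamma = NULL, social_const = 0) {
  ep <- calibrate_activity(profile, expenditure)
  g <- gamma %||% profile$gamma
  ip <- intake_params(g, profile$intake0_kcal, profile$mass0_kg)
  fn <- function(m) {
    I <- intake_update(ip, m)
    I - total_expenditure(profile$sex, profile$age_years, m, I, ep) +
      social_const
  }
  m0 <- profile$mass0_kg
  f0 <- fn(m0)
  if (f0 == 0) return(m0)
  dir <- sign(f0)  # positive imbalance -> mass grows
  lo <- hi <- m0
  step <- 0.02 * m0
  repeat {
    cand <- if (dir > 0) hi + step else lo - step
    if (cand <= 0.5 || cand > 1000) {
      stop("no equilibrium mass found in a physiological range", call. = FALSE)
    }
    if (sign(fn(cand)) != sign(f0)) {
      if (dir > 0) hi <- cand else lo <- cand
      break
    }
    if (dir > 0) hi <- cand else lo <- cand
  }
  stats::uniroot(fn, lower = lo, upper = hi, tol = 1e-10)$root
}

#' Days until the trajectory is within a mass tolerance of its target
#'
#' @param traj A `trajectory`.
#' @param target_mass Stability target, kg; defaults to the trajectory's final
#'   mass.
#' @param tol_kg Mass tolerance, kg.
#' @return First day index with `|m(t) - target| < tol_kg` (NA if never).
#' @export
time_to_stability <- function(traj, target_mass = NULL, tol_kg = 0.1) {
  target <- target_mass %||% traj$mass_kg[nrow(traj)]
  hit <- which(abs(traj$mass_kg - target) < tol_kg)
  if (length(hit) == 0L) NA_integer_ else traj$day[hit[1L]]
}

#' First day the personal energy gap falls below a tolerance
#'
#' @param traj A `trajectory`.
#' @param tol_kcal Gap tolerance, kcal/day.
#' @return Day index, or NA.
#' @export
stable_day <- function(traj, tol_kcal = 0.5) {
  gap <- abs(traj$intake_kcal - traj$expend_kcal)
  hit <- which(gap < tol_kcal & traj$day > 0)
  if (length(hit) == 0L) NA_integer_ else traj$day[hit[1L]]
}

#' Variance of the daily mass increments over the trajectory tail
#'
#' Used to quantify how much stochastic social interaction amplifies the
#' day-to-day fluctuation of body mass once the trajectory has flattened.
#'
#' @param traj A `trajectory`.
#' @param tail_frac Fraction of the horizon to use, from the end.
#' @return Sample variance of `diff(mass_kg)` over the tail, kg^2.
#' @export
increment_variance <- function(traj, tail_frac = 0.2) {
  n <- nrow(traj)
  k <- max(3L, ceiling(tail_frac * n))
  stats::var(diff(traj$mass_kg[(n - k + 1L):n]))
}

#' Audit the cumulative energy budget of a run
#'
#' Checks that the energy stored in (or released from) the two compartments
#' matches the cumulative effective imbalance, day by day:
#' `cumsum(rho_F * dF + rho_L * dL) == cumsum(I - E + social)`. Clamped
#' terminal records (where conservation is deliberately broken to keep the
#' compartments non-negative) are excluded.
#'
#' @param traj A `trajectory`.
#' @return Maximum absolute relative discrepancy over the run.
#' @export
audit_conservation <- function(traj) {
  dens <- attr(traj, "config")$model$densities
  keep <- !traj$clamped
  stored <- dens$rho_F * diff(traj$fat_kg) + dens$rho_L * diff(traj$lean_kg)
  imb <- (traj$intake_kcal - traj$expend_kcal + traj$social_kcal)[-1L]
  i <- which(keep[-1L])
  lhs <- cumsum(stored[i])
  rhs <- cumsum(imb[i])
  max(abs(lhs - rhs) / pmax(abs(rhs), 1))
}

#' Recover the intake responsiveness from an observed mass trajectory
#'
#' Re-simulates the deterministic model over a grid of `gamma` values and
#' returns the grid point minimising the sum of squared deviations from the
#' observed daily masses.
#'
#' @param mass_obs Observed daily masses (day 0 first), or a `trajectory`.
#' @param profile The [individual_profile()] that generated the observation
#'   (its `gamma` is ignored).
#' @param gammas Candidate grid; defaults to the conventional 0.1--0.5 range
#'   in steps of 0.05.
#' @param ... Additional arguments to [run_config()] (e.g. `p_kind`).
#' @return The best-fitting `gamma`; the full grid of sums of squares is
#'   attached as attribute `"sse"`.
#' @export
estimate_gamma <- function(mass_obs, profile,
                           gammas = seq(0.1, 0.5, by = 0.05), ...) {
  if (inherits(mass_obs, "trajectory")) mass_obs <- mass_obs$mass_kg
  horizon <- length(mass_obs) - 1L
  sse <- vapply(gammas, function(g) {
    sim <- simulate_individual(run_config(profile, horizon_days = horizon,
                                          gamma = g, ...))
    k <- min(nrow(sim), length(mass_obs))
    sum((sim$mass_kg[seq_len(k)] - mass_obs[seq_len(k)])^2)
  }, numeric(1))
  best <- gammas[which.min(sse)]
  attr(best, "sse") <- stats::setNames(sse, gammas)
  best
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' @param traj A `trajectory`.
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.meta.json` (seed, status, profile and model settings).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c(
    "day", "fat_kg", "lean_kg", "mass_kg", "intake_kcal", "expend_kcal",
    "social_kcal", "clamped", "negative_fat"
  )], path, row.names = FALSE)
  cfg <- attr(traj, "config")
  prof <- attr(traj, "profile")
  meta <- list(
    package = "massdyn",
    version = as.character(utils::packageVersion("massdyn")),
    status = attr(traj, "status"),
    seed = attr(traj, "seed"),
    horizon_days = cfg$horizon_days,
    p_kind = cfg$model$p_kind,
    densities = cfg$model$densities[c("rho_F", "rho_L")],
    forbes_C_kg = cfg$model$forbes_C_kg,
    social = unclass(cfg$social),
    profile = prof[c("id", "sex", "age_years", "height_m", "mass0_kg",
                     "fat0_kg", "lean0_kg", "intake0_kcal", "expend0_kcal",
                     "gamma")]
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
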