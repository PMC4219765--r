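#' Immutable initial conditions for one simulated individual
#'
#' @param id Identifier (integer or character).
#' @param sex `"male"` or `"female"`.
#' @param age_years Adult age in years.
#' @param height_m Height in m.
#' @param mass0_kg Initial total body mass, kg.
#' @param fat0_kg Initial fat mass, kg (lean mass is derived).
#' @param intake0_kcal Initial daily caloric intake, kcal/day.
#' @param expend0_kcal Initial daily total energy expenditure, kcal/day.
#' @param gamma Intake responsiveness exponent in `[0, 1]`.
#' @param fat_bounds Plausibility bounds on the fat fraction.
#' @param max_gap_kcal Largest allowed `|intake0 - expend0|`, kcal/day; the
#'   default 300 reflects the observed spread of individual energy gaps.
#' @param meta Optional named list of free-form metadata.
#' @return An object of class `individual_profile` with derived `lean0_kg`,
#'   `fat0_frac` and `bmi0`.
#' @export
#' @examples
#' individual_profile(1, "male", 30.43, 1.88, 72.06, 12.96,
#'                    2821.48, 3248.75, gamma = 0.32)
individual_profile <- function(id, sex, age_years, height_m, mass0_kg,
                               fat0_kg, intake0_kcal, expend0_kcal, gamma,
                               fat_bounds = c(0.05, 0.55),
                               max_gap_kcal = 300, meta = list()) {
  sex <- match_sex(sex)
  for (nm in c("age_years", "height_m", "mass0_kg", "fat0_kg",
               "intake0_kcal", "expend0_kcal", "gamma")) {
    stopifnot_scalar(get(nm), nm)
  }
  if (height_m <= 0) stop("`height_m` must be > 0", call. = FALSE)
  if (mass0_kg <= 0) stop("`mass0_kg` must be > 0", call. = FALSE)
  lean0 <- mass0_kg - fat0_kg
  if (fat0_kg <= 0 || lean0 <= 0) {
    stop("initial fat and lean masses must both be > 0", call. = FALSE)
  }
  frac <- fat0_kg / mass0_kg
  if (frac < fat_bounds[1] || frac > fat_bounds[2]) {
    stop(sprintf("fat fraction %.3f outside plausible bounds [%g, %g]",
                 frac, fat_bounds[1], fat_bounds[2]), call. = FALSE)
  }
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]", call. = FALSE)
  if (abs(intake0_kcal - expend0_kcal) > max_gap_kcal) {
    stop(sprintf("initial energy gap %.1f kcal/day exceeds +/-%g",
                 intake0_kcal - expend0_kcal, max_gap_kcal), call. = FALSE)
  }
  structure(
    list(
      id = id, sex = sex, age_years = age_years, height_m = height_m,
      mass0_kg = mass0_kg, fat0_kg = fat0_kg, lean0_kg = lean0,
      fat0_frac = frac, bmi0 = mass0_kg / height_m^2,
      intake0_kcal = intake0_kcal, expend0_kcal = expend0_kcal,
      gamma = gamma, meta = meta
    ),
    class = "individual_profile"
  )
}

#' @export
print.individual_profile <- function(x, ...) {
  cat(sprintf(
    paste0("<individual_profile %s> %s, %.1f y, %.2f m\n",
           "  mass %.2f kg (fat %.2f, lean %.2f; BMI %.1f)\n",
           "  intake %.2f kcal/d, expenditure %.2f kcal/d, gamma %.2f\n"),
    as.character(x$id), x$sex, x$age_years, x$height_m,
    x$mass0_kg, x$fat0_kg, x$lean0_kg, x$bmi0,
    x$intake0_kcal, x$expend0_kcal, x$gamma
  ))
  invisible(x)
}

#' Worked example individuals
#'
#' Returns one of four published example individuals used throughout the
#' scenario presets: two men undergoing large weight changes (used to contrast
#' the Forbes and Hall partition rules) and a weight-losing man / weight-gaining
#' woman pair (used for the intake-responsiveness and social-interaction
#' experiments).
#'
#' The `fig2` preset's printed initial expenditure (29991.30 kcal/day) is a
#' physiologically impossible value, treated as a misprint of 2999.13; the
#' original figure is kept in `meta$expend0_as_printed`.
#'
#' @param preset One of `"fig1"`, `"fig2"`, `"fig3"`, `"fig4"`.
#' @return An [individual_profile()].
#' @export
#' @examples
#' profile_from_caption("fig3")
profile_from_caption <- function(preset = c("fig1", "fig2", "fig3", "fig4")) {
  preset <- match.arg(preset)
  switch(preset,
    fig1 = individual_profile(
      "fig1", "male", 30.43, 1.88, mass0_kg = 72.06, fat0_kg = 12.96,
      intake0_kcal = 2821.48, expend0_kcal = 3248.75, gamma = 0.32,
      max_gap_kcal = Inf
    ),
    fig2 = individual_profile(
      "fig2", "male", 20.26, 1.89, mass0_kg = 74.69, fat0_kg = 12.69,
      intake0_kcal = 3288.08, expend0_kcal = 2999.13, gamma = 0.44,
      max_gap_kcal = Inf,
      meta = list(expend0_as_printed = 29991.30)
    ),
    fig3 = individual_profile(
      "fig3", "male", 38.44, 1.76, mass0_kg = 99.52,
      fat0_kg = 0.3711 * 99.52,
      intake0_kcal = 3506.32, expend0_kcal = 3527.51, gamma = 0.30
    ),
    fig4 = individual_profile(
      "fig4", "female", 34.54, 1.54, mass0_kg = 50.01,
      fat0_kg = 0.2040 * 50.01,
      intake0_kcal = 2196.22, expend0_kcal = 2187.62, gamma = 0.30
    )
  )
}

#' Configuration of the synthetic-population generator
#'
#' The generator emulates survey-style adult energy distributions without any
#' external data: anthropometrics are drawn per sex (height normal, BMI and
#' fat fraction truncated normal), expenditure is built as basal rate times a
#' physical activity level `PAL ~ U(pal_range)`, and intake is expenditure
#' plus a symmetric `U(gap_range)` energy gap. All defaults are configurable
#' placeholders for generic adult populations, not a specific country.
#'
#' @param sex_prob Probability that an individual is male.
#' @param age_range Uniform age range in years (adult brackets only).
#' @param height_mean,height_sd Named (`male`, `female`) means/sds of height, m.
#' @param bmi_mean,bmi_sd,bmi_bounds Truncated-normal BMI parameters.
#' @param fat_frac_mean,fat_frac_sd Named fat-fraction parameters by sex.
#' @param fat_bounds Truncation bounds of the fat fraction.
#' @param pal_range Uniform range of the physical activity level.
#' @param gap_range Uniform range of `intake0 - expend0`, kcal/day.
#' @param gamma_range Uniform range of the intake responsiveness `gamma`.
#' @param beta_thermo Thermogenesis fraction used for feasibility checks.
#' @return A list of class `pop_config`.
#' @export
pop_config <- function(sex_prob = 0.5,
                       age_range = c(18, 60),
                       height_mean = c(male = 1.76, female = 1.62),
                       height_sd = c(male = 0.07, female = 0.07),
                       bmi_mean = 26, bmi_sd = 5, bmi_bounds = c(16, 45),
                       fat_frac_mean = c(male = 0.25, female = 0.33),
                       fat_frac_sd = c(male = 0.08, female = 0.08),
                       fat_bounds = c(0.05, 0.55),
                       pal_range = c(1.4, 2.0),
                       gap_range = c(-300, 300),
                       gamma_range = c(0.1, 0.5),
                       beta_thermo = 0.10) {
  cfg <- list(
    sex_prob = sex_prob, age_range = age_range,
    height_mean = height_mean, height_sd = height_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_bounds = bmi_bounds,
    fat_frac_mean = fat_frac_mean, fat_frac_sd = fat_frac_sd,
    fat_bounds = fat_bounds, pal_range = pal_range,
    gap_range = gap_range, gamma_range = gamma_range,
    beta_thermo = beta_thermo
  )
  if (gap_range[1] > gap_range[2] || max(abs(gap_range)) > 300) {
    stop("`gap_range` must be an interval within [-300, 300]", call. = FALSE)
  }
  if (pal_range[1] < 1.15) {
    # PAL below ~1.15 cannot cover thermogenesis plus the largest positive
    # energy gap for small individuals: the implied activity would be negative.
    stop("`pal_range` too low: implied activity cost can be negative",
         call. = FALSE)
  }
  class(cfg) <- "pop_config"
  cfg
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Generate a synthetic population of initial conditions
#'
#' Draws `n` individuals from the configured distributions. Every profile
#' satisfies the [individual_profile()] invariants by construction: the fat
#' fraction is truncated to its bounds, the intake-expenditure gap is bounded
#' by `gap_range`, and the activity calibration is guaranteed feasible
#' (`PAL >= 1.4` leaves room for thermogenesis plus the largest positive gap).
#'
#' @param n Number of individuals (>= 1).
#' @param config A [pop_config()].
#' @param seed Optional integer seed for exact reproducibility.
#' @param bmr_table Basal-rate coefficient table.
#' @return A data frame of class `population` with one row per individual:
#'   `id, sex, age_years, height_m, mass0_kg, fat0_kg, lean0_kg,
#'   intake0_kcal, expend0_kcal, gamma`.
#' @export
#' @examples
#' generate_population(5, seed = 1)
generate_population <- function(n, config = pop_config(), seed = NULL,
                                bmr_table = fao_bmr_table()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(inherits(config, "pop_config"))
  with_seed(seed, {
    sex <- ifelse(stats::runif(n) < config$sex_prob, "male", "female")
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    height <- ifelse(
      sex == "male",
      rtruncnorm(n, config$height_mean[["male"]], config$height_sd[["male"]],
                 1.40, 2.10),
      rtruncnorm(n, config$height_mean[["female"]], config$height_sd[["female"]],
                 1.40, 2.10)
    )
    bmi <- rtruncnorm(n, config$bmi_mean, config$bmi_sd,
                      config$bmi_bounds[1], config$bmi_bounds[2])
    mass <- bmi * height^2
    frac <- ifelse(
      sex == "male",
      rtruncnorm(n, config$fat_frac_mean[["male"]], config$fat_frac_sd[["male"]],
                 config$fat_bounds[1], config$fat_bounds[2]),
      rtruncnorm(n, config$fat_frac_mean[["female"]],
                 config$fat_frac_sd[["female"]],
                 config$fat_bounds[1], config$fat_bounds[2])
    )
    fat <- frac * mass
    ep <- expenditure_params(beta_thermo = config$beta_thermo,
                             bmr_table = bmr_table)
    bmr <- vapply(seq_len(n), function(i) {
      basal_expenditure(sex[i], age[i], mass[i], ep)
    }, numeric(1))
    pal <- stats::runif(n, config$pal_range[1], config$pal_range[2])
    expend <- bmr * pal
    gap <- stats::runif(n, config$gap_range[1], config$gap_range[2])
    intake <- expend + gap
    gamma <- stats::runif(n, config$gamma_range[1], config$gamma_range[2])
    out <- data.frame(
      id = seq_len(n), sex = sex, age_years = age, height_m = height,
      mass0_kg = mass, fat0_kg = fat, lean0_kg = mass - fat,
      intake0_kcal = intake, expend0_kcal = expend, gamma = gamma,
      stringsAsFactors = FALSE
    )
    class(out) <- c("population", "data.frame")
    out
  })
}

#' Turn one population row into an individual profile
#'
#' @param population A [generate_population()] data frame.
#' @param i Row index.
#' @return An [individual_profile()].
#' @export
as_profile <- function(population, i = 1L) {
  r <- population[i, , drop = FALSE]
  individual_profile(
    r$id, r$sex, r$age_years, r$height_m, r$mass0_kg, r$fat0_kg,
    r$intake0_kcal, r$expend0_kcal, r$gamma
  )
}

#' Write / read a population table
#'
#' Populations round-trip as plain CSV (one row per profile, documented
#' header) or JSON.
#'
#' @param population A population data frame.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `write_population()` returns `path` invisibly; `read_population()`
#'   returns the population data frame.
#' @export
write_population <- function(population, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(population), path, digits = NA)
  } else {
    utils::write.csv(as.data.frame(population), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  out <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  class(out) <- c("population", "data.frame")
  out
}
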