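#' FAO/WHO/UNU adult basal-metabolic-rate coefficient table
#'
#' Weight-based (Schofield) linear equations `BMR = slope * W + intercept`
#' in kcal/day, by sex and adult age bracket. Ages in `[age_min, age_max)`
#' except the last bracket of each sex, which is closed above.
#'
#' @return A data frame with columns `sex`, `age_min`, `age_max`, `slope`,
#'   `intercept`.
#' @export
#' @examples
#' fao_bmr_table()
fao_bmr_table <- function() {
  data.frame(
    sex = c("male", "male", "female", "female"),
    age_min = c(18, 30, 18, 30),
    age_max = c(30, 60, 30, 60),
    slope = c(15.057, 11.472, 14.818, 8.126),
    intercept = c(692.2, 873.1, 486.6, 845.6),
    stringsAsFactors = FALSE
  )
}

#' Parameters of the total-energy-expenditure decomposition
#'
#' Total expenditure is `E(t) = B(sex, age, m) + beta * I(t) + A(m)`, with
#' `B` the basal rate from the coefficient table, `beta * I` diet-induced
#' thermogenesis, and activity either proportional to mass
#' (`A = activity_per_kg * m`, the default) or constant
#' (`A = activity_const`). The activity level is calibrated once from the
#' initial conditions via [calibrate_activity()], so that only known
#' quantities enter the model.
#'
#' @param beta_thermo Thermogenesis fraction of intake, in `[0, 0.3)`.
#'   Default 0.10, the usual diet-induced-thermogenesis convention.
#' @param bmr_table Coefficient table in the format of [fao_bmr_table()].
#' @param activity_model `"per_kg"` (activity cost proportional to mass) or
#'   `"constant"`.
#' @param activity_per_kg Activity cost per kg per day (set by calibration).
#' @param activity_const Constant activity cost, kcal/day (set by calibration).
#' @return An object of class `expenditure_params`.
#' @export
expenditure_params <- function(beta_thermo = 0.10,
                               bmr_table = fao_bmr_table(),
                               activity_model = c("per_kg", "constant"),
                               activity_per_kg = NA_real_,
                               activity_const = NA_real_) {
  stopifnot_scalar(beta_thermo, "beta_thermo")
  if (beta_thermo < 0 || beta_thermo >= 0.3) {
    stop("`beta_thermo` must lie in [0, 0.3)", call. = FALSE)
  }
  need <- c("sex", "age_min", "age_max", "slope", "intercept")
  if (!is.data.frame(bmr_table) || !all(need %in% names(bmr_table))) {
    stop("`bmr_table` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      beta_thermo = beta_thermo,
      bmr_table = bmr_table,
      activity_model = match.arg(activity_model),
      activity_per_kg = activity_per_kg,
      activity_const = activity_const
    ),
    class = "expenditure_params"
  )
}

#' Basal energy expenditure
#'
#' Linear-in-mass basal metabolic rate from the sex- and age-bracket-specific
#' coefficient table.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_years Age in years; only the adult brackets of the table are
#'   supported.
#' @param mass_kg Body mass, kg.
#' @param params An [expenditure_params()] object (supplies the table).
#' @return Basal expenditure, kcal/day.
#' @export
#' @examples
#' basal_expenditure("male", 38.44, 99.52, expenditure_params())
basal_expenditure <- function(sex, age_years, mass_kg,
                              params = expenditure_params()) {
  sex <- match_sex(sex)
  stopifnot_scalar(age_years, "age_years")
  stopifnot_scalar(mass_kg, "mass_kg")
  if (mass_kg <= 0) stop("`mass_kg` must be > 0", call. = FALSE)
  tab <- params$bmr_table[params$bmr_table$sex == sex, , drop = FALSE]
  last_max <- max(tab$age_max)
  hit <- which(age_years >= tab$age_min &
                 (age_years < tab$age_max |
                    (tab$age_max == last_max & age_years == last_max)))
  if (length(hit) == 0L) {
    stop(sprintf(
      "no basal-rate bracket for %s aged %.1f; supported brackets: %s",
      sex, age_years,
      paste(sprintf("[%g, %g)", tab$age_min, tab$age_max), collapse = ", ")
    ), call. = FALSE)
  }
  row <- tab[hit[1L], ]
  row$slope * mass_kg + row$intercept
}

#' Diet-induced thermogenesis
#'
#' @param intake_kcal Daily caloric intake, kcal/day (>= 0).
#' @param beta Thermogenesis fraction.
#' @return `beta * intake_kcal`, kcal/day.
#' @export
thermogenesis <- function(intake_kcal, beta = 0.10) {
  if (any(!is.finite(intake_kcal)) || any(intake_kcal < 0)) {
    stop("`intake_kcal` must be finite and >= 0", call. = FALSE)
  }
  beta * intake_kcal
}

#' Dynamic caloric-intake parameters
#'
#' @param gamma Responsiveness of intake to relative body-mass change,
#'   dimensionless in `[0, 1]`. Individuals are conventionally drawn from
#'   (0.1, 0.5); larger values make intake track mass more strongly, which
#'   lengthens the time to equilibrium.
#' @param intake0_kcal Initial daily intake, kcal/day.
#' @param mass0_kg Initial body mass, kg.
#' @return An object of class `intake_params`.
#' @export
intake_params <- function(gamma, intake0_kcal, mass0_kg) {
  stopifnot_scalar(gamma, "gamma")
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]", call. = FALSE)
  stopifnot_scalar(intake0_kcal, "intake0_kcal")
  if (intake0_kcal < 0) stop("`intake0_kcal` must be >= 0", call. = FALSE)
  stopifnot_scalar(mass0_kg, "mass0_kg")
  if (mass0_kg <= 0) stop("`mass0_kg` must be > 0", call. = FALSE)
  structure(
    list(gamma = gamma, intake0_kcal = intake0_kcal, mass0_kg = mass0_kg),
    class = "intake_params"
  )
}

#' Dynamic caloric intake
#'
#' `I(t) = I(t0) * (m(t)/m(t0))^gamma`: intake follows the body mass with
#' per-individual responsiveness `gamma`. At `m = m0` the intake equals its
#' initial value, and `gamma = 0` decouples intake from mass entirely.
#'
#' @param params An [intake_params()] object.
#' @param mass_kg Current body mass, kg (> 0). Vectorized.
#' @return Intake, kcal/day.
#' @export
#' @examples
#' intake_update(intake_params(0.3, 3506.32, 99.52), 90)
intake_update <- function(params, mass_kg) {
  stopifnot(inherits(params, "intake_params"))
  if (!is.numeric(mass_kg) || any(!is.finite(mass_kg))) {
    stop("`mass_kg` must be finite", call. = FALSE)
  }
  if (any(mass_kg <= 0)) stop("`mass_kg` must be > 0", call. = FALSE)
  params$intake0_kcal * (mass_kg / params$mass0_kg)^params$gamma
}

#' Calibrate the activity cost from the initial conditions
#'
#' Solves the expenditure decomposition at the initial time for the activity
#' term, so that the model reproduces the observed initial expenditure
#' exactly: `delta = (E0 - B0 - beta * I0) / m0` under the per-kg model, or
#' `A0 = E0 - B0 - beta * I0` under the constant model.
#'
#' @param profile An [individual_profile()] (or any list with `sex`,
#'   `age_years`, `mass0_kg`, `intake0_kcal`, `expend0_kcal`).
#' @param params An [expenditure_params()] object.
#' @return `params` with the activity level filled in.
#' @export
#' @examples
#' p <- profile_from_caption("fig3")
#' calibrate_activity(p, expenditure_params())$activity_per_kg
calibrate_activity <- function(profile, params = expenditure_params()) {
  stopifnot(inherits(params, "expenditure_params"))
  b0 <- basal_expenditure(profile$sex, profile$age_years, profile$mass0_kg,
                          params)
  a0 <- profile$expend0_kcal - b0 - params$beta_thermo * profile$intake0_kcal
  if (a0 < 0) {
    stop(sprintf(
      paste0("initial conditions are inconsistent: E0 = %.2f is below basal ",
             "plus thermogenesis (%.2f), implying negative activity"),
      profile$expend0_kcal, b0 + params$beta_thermo * profile$intake0_kcal
    ), call. = FALSE)
  }
  if (params$activity_model == "per_kg") {
    params$activity_per_kg <- a0 / profile$mass0_kg
  } else {
    params$activity_const <- a0
  }
  params
}

#' Total energy expenditure
#'
#' `E(t) = B(sex, age, m) + beta * I(t) + A(m)`, with the activity term taken
#' from the calibrated parameters. Strictly increasing in mass at fixed
#' intake.
#'
#' @inheritParams basal_expenditure
#' @param intake_kcal Current daily intake, kcal/day.
#' @param params A calibrated [expenditure_params()] object (see
#'   [calibrate_activity()]).
#' @return Total expenditure, kcal/day.
#' @export
total_expenditure <- function(sex, age_years, mass_kg, intake_kcal, params) {
  stopifnot(inherits(params, "expenditure_params"))
  act <- if (params$activity_model == "per_kg") {
    if (is.na(params$activity_per_kg)) {
      stop("activity cost not calibrated; run calibrate_activity() first",
           call. = FALSE)
    }
    params$activity_per_kg * mass_kg
  } else {
    if (is.na(params$activity_const)) {
      stop("activity cost not calibrated; run calibrate_activity() first",
           call. = FALSE)
    }
    params$activity_const
  }
  basal_expenditure(sex, age_years, mass_kg, params) +
    thermogenesis(intake_kcal, params$beta_thermo) + act
}
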