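#' Energy densities of the body compartments
#'
#' The two-compartment model stores every energy imbalance as fat or lean
#' tissue with fixed energy densities. The defaults (9400 kcal/kg for fat,
#' 1800 kcal/kg for lean tissue) are the standard values of the Chow--Hall
#' energy-partition literature.
#'
#' @param rho_F Energy density of body fat, kcal per kg.
#' @param rho_L Energy density of lean tissue, kcal per kg. Must satisfy
#'   `rho_F > rho_L > 0`.
#' @return An object of class `energy_densities`.
#' @export
#' @examples
#' energy_densities()
energy_densities <- function(rho_F = 9400, rho_L = 1800) {
  stopifnot_scalar(rho_F, "rho_F")
  stopifnot_scalar(rho_L, "rho_L")
  if (!(rho_F > rho_L && rho_L > 0)) {
    stop("energy densities must satisfy rho_F > rho_L > 0", call. = FALSE)
  }
  structure(list(rho_F = rho_F, rho_L = rho_L), class = "energy_densities")
}

#' Partition model: how the daily imbalance is split between fat and lean
#'
#' Under the Forbes rule the fraction of imbalance energy routed to the lean
#' compartment is `p = C/(C + F)` with `F` the current fat mass; the Forbes
#' constant defaults to `C = 10.4 * rho_L / rho_F` kg, the form the Forbes
#' lean--fat companionship curve takes once expressed in energy-partition
#' terms. Under the Hall rule `p` is the realized lean share `dL/dM` of the
#' previous day's mass change (see [hall_p()]); it is applied as a mass share,
#' is not clamped to `[0, 1]`, and can drive the fat compartment negative --
#' a model pathology the simulator records rather than hides.
#'
#' @param densities An [energy_densities()] object.
#' @param forbes_C_kg Forbes constant C in kg, > 0.
#' @param p_kind `"forbes"` or `"hall"`.
#' @return An object of class `partition_model`.
#' @export
partition_model <- function(densities = energy_densities(),
                            forbes_C_kg = 10.4 * densities$rho_L / densities$rho_F,
                            p_kind = c("forbes", "hall")) {
  stopifnot(inherits(densities, "energy_densities"))
  stopifnot_scalar(forbes_C_kg, "forbes_C_kg")
  if (forbes_C_kg <= 0) stop("`forbes_C_kg` must be > 0", call. = FALSE)
  p_kind <- match.arg(p_kind)
  structure(
    list(densities = densities, forbes_C_kg = forbes_C_kg, p_kind = p_kind),
    class = "partition_model"
  )
}

#' Body composition state
#'
#' @param fat_kg Fat mass in kg. May be negative only as the recorded outcome
#'   of a Hall-rule run; the constructor does not forbid it.
#' @param lean_kg Lean mass in kg, > 0.
#' @param height_m Optional height in m, used to derive BMI.
#' @return An object of class `body_state` with derived `mass_kg` and `bmi`.
#' @export
#' @examples
#' body_state(fat_kg = 12.96, lean_kg = 59.09, height_m = 1.88)
body_state <- function(fat_kg, lean_kg, height_m = NA_real_) {
  stopifnot_scalar(fat_kg, "fat_kg")
  stopifnot_scalar(lean_kg, "lean_kg")
  if (lean_kg <= 0) stop("`lean_kg` must be > 0", call. = FALSE)
  mass <- fat_kg + lean_kg
  if (mass <= 0) stop("total mass must be > 0", call. = FALSE)
  structure(
    list(
      fat_kg = fat_kg, lean_kg = lean_kg, mass_kg = mass,
      height_m = height_m,
      bmi = if (is.na(height_m)) NA_real_ else mass / height_m^2
    ),
    class = "body_state"
  )
}

#' @export
print.body_state <- function(x, ...) {
  cat(sprintf(
    "<body_state> mass %.2f kg (fat %.2f, lean %.2f)%s\n",
    x$mass_kg, x$fat_kg, x$lean_kg,
    if (is.na(x$bmi)) "" else sprintf(", BMI %.1f", x$bmi)
  ))
  invisible(x)
}

#' Forbes lean-energy partition fraction
#'
#' `p = C / (C + F)`: the fraction of the daily energy imbalance routed to the
#' lean compartment falls as fat mass rises, so heavier-fat individuals store
#' (or release) proportionally more energy as fat.
#'
#' @param fat_kg Fat mass in kg, > 0. Vectorized.
#' @param model A [partition_model()].
#' @return Partition fraction(s) in (0, 1).
#' @export
#' @examples
#' forbes_p(12.96, partition_model())
forbes_p <- function(fat_kg, model = partition_model()) {
  stopifnot(inherits(model, "partition_model"))
  if (!is.numeric(fat_kg) || length(fat_kg) < 1L || any(!is.finite(fat_kg))) {
    stop("`fat_kg` must be finite", call. = FALSE)
  }
  if (any(fat_kg <= 0)) {
    stop("`fat_kg` must be > 0 for the Forbes relation", call. = FALSE)
  }
  model$forbes_C_kg / (model$forbes_C_kg + fat_kg)
}

#' First-difference (Hall-type) partition ratio
#'
#' Returns the realized lean share of the previous day's mass change,
#' `p = dL/dM`. When the mass change is numerically degenerate
#' (`|dM| < tol`), the supplied fallback is returned so that the recursion can
#' be (re)seeded, conventionally from a Forbes-consistent step. The result is
#' deliberately not clamped to `[0, 1]`: out-of-range ratios are part of the
#' model's recorded behaviour.
#'
#' @param delta_L Lean-mass change over the previous step, kg.
#' @param delta_M Total-mass change over the previous step, kg.
#' @param fallback_p Ratio to use when `|delta_M| < tol`.
#' @param tol Degeneracy tolerance on `|delta_M|`, kg.
#' @return The partition ratio (unclamped).
#' @export
#' @examples
#' hall_p(-0.2, -0.5, fallback_p = 0.4)
hall_p <- function(delta_L, delta_M, fallback_p, tol = 1e-9) {
  stopifnot_scalar(delta_L, "delta_L")
  stopifnot_scalar(delta_M, "delta_M")
  stopifnot_scalar(fallback_p, "fallback_p")
  if (abs(delta_M) < tol) fallback_p else delta_L / delta_M
}

#' Raw compartment increments for a daily energy imbalance
#'
#' Vectorized over `imbalance_kcal` and `p`. Two bases are supported:
#' \describe{
#'   \item{`"energy"`}{`p` is the lean *energy* fraction (Forbes usage):
#'     `dL = p * imb * dt / rho_L`, `dF = (1 - p) * imb * dt / rho_F`.}
#'   \item{`"mass"`}{`p` is the lean *mass* share (first-difference Hall
#'     usage): `dM = imb * dt / (p * rho_L + (1 - p) * rho_F)`,
#'     `dL = p * dM`, `dF = (1 - p) * dM`.}
#' }
#' Both satisfy `rho_F * dF + rho_L * dL = imb * dt` identically.
#'
#' @param imbalance_kcal Daily energy imbalance(s), kcal/day.
#' @param p Lean partition fraction(s).
#' @param densities An [energy_densities()] object.
#' @param basis `"energy"` or `"mass"`.
#' @param dt Time step, days.
#' @return List with numeric vectors `dF` and `dL` (kg).
#' @export
partition_deltas <- function(imbalance_kcal, p, densities,
                             basis = c("energy", "mass"), dt = 1) {
  basis <- match.arg(basis)
  if (any(!is.finite(imbalance_kcal))) {
    stop("energy imbalance must be finite (got NaN/Inf)", call. = FALSE)
  }
  if (any(!is.finite(p))) stop("partition fraction must be finite", call. = FALSE)
  if (basis == "energy") {
    dL <- p * imbalance_kcal * dt / densities$rho_L
    dF <- (1 - p) * imbalance_kcal * dt / densities$rho_F
  } else {
    rho_bar <- p * densities$rho_L + (1 - p) * densities$rho_F
    if (any(abs(rho_bar) < 1e-8)) {
      stop("degenerate effective energy density in mass-share partition",
           call. = FALSE)
    }
    dM <- imbalance_kcal * dt / rho_bar
    dL <- p * dM
    dF <- (1 - p) * dM
  }
  list(dF = dF, dL = dL)
}

#' Advance the body composition by one daily Euler step
#'
#' Splits the daily energy imbalance `I - E` between the fat and lean
#' compartments and advances the state by one time step (default 1 day).
#' The split satisfies exact energy conservation,
#' `rho_F * dF + rho_L * dL = (I - E) * dt`, in either basis.
#'
#' Under the Forbes model (`basis = "energy"`), a step that would take the fat
#' (or lean) compartment negative is clamped at zero and flagged
#' (`attr(, "clamped")`), signalling terminal emaciation; under the Hall model
#' (`basis = "mass"`) no clamping is applied and a negative fat mass is
#' recorded and flagged (`attr(, "negative_fat")`).
#'
#' @param state A [body_state()].
#' @param imbalance_kcal Daily energy imbalance `I - E` (+ any social term),
#'   kcal/day. Must be finite.
#' @param p Partition fraction (lean share), from [forbes_p()] or [hall_p()].
#' @param model A [partition_model()]; supplies the energy densities and the
#'   default basis (`"energy"` for Forbes, `"mass"` for Hall).
#' @param basis Override of the partition basis; defaults per `p_kind`.
#' @param dt Time step in days.
#' @return A new `body_state` with attributes `clamped` and `negative_fat`.
#' @export
#' @examples
#' st <- body_state(12.96, 59.09, 1.88)
#' partition_step(st, imbalance_kcal = -427.27, p = 0.1332, partition_model())
partition_step <- function(state, imbalance_kcal, p, model,
                           basis = NULL, dt = 1) {
  stopifnot(inherits(state, "body_state"), inherits(model, "partition_model"))
  stopifnot_scalar(imbalance_kcal, "imbalance_kcal")
  stopifnot_scalar(p, "p")
  basis <- basis %||% if (model$p_kind == "hall") "mass" else "energy"
  d <- partition_deltas(imbalance_kcal, p, model$densities, basis = basis, dt = dt)
  fat <- state$fat_kg + d$dF
  lean <- state$lean_kg + d$dL
  clamped <- FALSE
  if (model$p_kind == "forbes") {
    if (fat < 0 || lean <= 0) {
      clamped <- TRUE
      fat <- max(fat, 0)
      lean <- max(lean, 1e-6)
    }
  }
  out <- structure(
    list(
      fat_kg = fat, lean_kg = lean, mass_kg = fat + lean,
      height_m = state$height_m,
      bmi = if (is.na(state$height_m)) NA_real_ else (fat + lean) / state$height_m^2
    ),
    class = "body_state"
  )
  attr(out, "clamped") <- clamped
  attr(out, "negative_fat") <- fat < 0
  out
}
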