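#' Social-interaction parameters
#'
#' The daily social perturbation of the energy balance is the signed product
#' of social proximity `alpha_s` (dimensionless, 0--1) and social influence
#' `epsilon` (kcal/day). Three experimental cases are supported besides
#' `"off"`:
#' \describe{
#'   \item{`fixed_proximity`}{`alpha_s` held fixed (conventionally 0.5) while
#'     the influence `epsilon` is swept, e.g. over 20--150 kcal/day.}
#'   \item{`fixed_influence`}{`epsilon` held fixed (conventionally +/-50
#'     kcal/day) while `alpha_s` is swept over 0--1.}
#'   \item{`random`}{each day, `alpha_s ~ U(0, 1)`,
#'     `epsilon ~ U(0, epsilon_max)` and the sign is drawn equiprobably.}
#' }
#' The default influence cap of 300 kcal/day matches the observed spread of
#' individual intake-expenditure gaps, which is on the order of 10--20% of
#' daily intake.
#'
#' @param case One of `"off"`, `"fixed_proximity"`, `"fixed_influence"`,
#'   `"random"`.
#' @param alpha_s Social proximity in `[0, 1]` (cases with fixed proximity).
#' @param epsilon_kcal Social influence magnitude in `[0, epsilon_max]`
#'   (cases with fixed influence).
#' @param sign_policy `"positive"`, `"negative"` or `"random"`; in case
#'   `"random"` the sign is redrawn independently each day.
#' @param epsilon_max Upper bound of the influence magnitude, kcal/day.
#' @return An object of class `social_params`.
#' @export
#' @examples
#' social_params("fixed_proximity", alpha_s = 0.5, epsilon_kcal = 100)
social_params <- function(case = c("off", "fixed_proximity",
                                   "fixed_influence", "random"),
                          alpha_s = 0.5, epsilon_kcal = 50,
                          sign_policy = c("positive", "negative", "random"),
                          epsilon_max = 300) {
  case <- match.arg(case)
  sign_policy <- match.arg(sign_policy)
  stopifnot_scalar(alpha_s, "alpha_s")
  stopifnot_scalar(epsilon_kcal, "epsilon_kcal")
  stopifnot_scalar(epsilon_max, "epsilon_max")
  if (alpha_s < 0 || alpha_s > 1) {
    stop("`alpha_s` must lie in [0, 1]", call. = FALSE)
  }
  if (epsilon_kcal < 0 || epsilon_kcal > epsilon_max) {
    stop(sprintf("`epsilon_kcal` must lie in [0, %g]", epsilon_max),
         call. = FALSE)
  }
  if (case == "random") sign_policy <- "random"
  structure(
    list(case = case, alpha_s = alpha_s, epsilon_kcal = epsilon_kcal,
         sign_policy = sign_policy, epsilon_max = epsilon_max),
    class = "social_params"
  )
}

#' Draw the daily social-interaction term
#'
#' Returns `sign * alpha_s * epsilon` in kcal/day. Deterministic in the fixed
#' cases (unless the sign policy is random); in case `"random"` the proximity,
#' influence and sign are each drawn fresh from the current RNG stream.
#'
#' @param params A [social_params()] object.
#' @param n Number of independent daily draws.
#' @return Numeric vector of length `n` (all zeros for case `"off"`).
#' @export
#' @examples
#' social_term(social_params("fixed_proximity", alpha_s = 0.5,
#'                           epsilon_kcal = 100))
social_term <- function(params, n = 1L) {
  stopifnot(inherits(params, "social_params"))
  if (params$case == "off") return(rep(0, n))
  alpha <- if (params$case == "random") stats::runif(n) else rep(params$alpha_s, n)
  eps <- if (params$case == "random") {
    stats::runif(n, 0, params$epsilon_max)
  } else {
    rep(params$epsilon_kcal, n)
  }
  sgn <- switch(params$sign_policy,
    positive = rep(1, n),
    negative = rep(-1, n),
    random = sample(c(-1, 1), n, replace = TRUE)
  )
  sgn * alpha * eps
}

#' Socially perturbed daily energy balance
#'
#' The net social energetic difference enters the daily balance as a single
#' signed term: `(I_ind - E_ind) + term`.
#'
#' @param I_ind Individual caloric intake, kcal/day (>= 0).
#' @param E_ind Individual total expenditure, kcal/day (>= 0).
#' @param term Signed social-interaction term, kcal/day.
#' @return Effective imbalance, kcal/day.
#' @export
#' @examples
#' perturbed_balance(2196.22, 2187.62, -50)
perturbed_balance <- function(I_ind, E_ind, term) {
  if (any(I_ind < 0) || any(E_ind < 0)) {
    stop("intake and expenditure must be >= 0", call. = FALSE)
  }
  (I_ind - E_ind) + term
}
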