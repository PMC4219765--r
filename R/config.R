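#' Build a run configuration from a YAML file
#'
#' The YAML file describes one run. Recognised keys:
#' \preformatted{
#' profile:
#'   preset: fig3            # OR the full field set of individual_profile():
#'   # id, sex, age_years, height_m, mass0_kg, fat0_kg,
#'   # intake0_kcal, expend0_kcal, gamma
#' horizon_days: 1500
#' p_kind: forbes            # or hall
#' gamma: 0.3                # optional override
#' densities: {rho_F: 9400, rho_L: 1800}
#' beta_thermo: 0.10
#' social:
#'   case: random            # off | fixed_proximity | fixed_influence | random
#'   alpha_s: 0.5
#'   epsilon_kcal: 50
#'   sign_policy: positive   # positive | negative | random
#' seed: 42
#' }
#'
#' @param path Path to the YAML file.
#' @return A [run_config()].
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$profile)) stop("config needs a `profile` block", call. = FALSE)
  prof <- if (!is.null(y$profile$preset)) {
    profile_from_caption(y$profile$preset)
  } else {
    do.call(individual_profile, y$profile)
  }
  dens <- if (is.null(y$densities)) energy_densities() else {
    energy_densities(rho_F = y$densities$rho_F %||% 9400,
                     rho_L = y$densities$rho_L %||% 1800)
  }
  social <- if (is.null(y$social)) social_params("off") else {
    social_params(
      case = y$social$case %||% "off",
      alpha_s = y$social$alpha_s %||% 0.5,
      epsilon_kcal = y$social$epsilon_kcal %||% 50,
      sign_policy = y$social$sign_policy %||% "positive",
      epsilon_max = y$social$epsilon_max %||% 300
    )
  }
  run_config(
    prof,
    horizon_days = y$horizon_days %||% 1500,
    p_kind = y$p_kind %||% "forbes",
    densities = dens,
    expenditure = expenditure_params(beta_thermo = y$beta_thermo %||% 0.10),
    social = social,
    gamma = y$gamma,
    seed = y$seed
  )
}

#' Build a population-generator configuration from a YAML file
#'
#' Any subset of the [pop_config()] arguments may appear as top-level keys;
#' the named sex-specific parameters are given as `{male: ..., female: ...}`
#' maps.
#'
#' @param path Path to the YAML file.
#' @return A [pop_config()].
#' @export
pop_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("sex_prob", "age_range", "bmi_mean", "bmi_sd", "bmi_bounds",
               "fat_bounds", "pal_range", "gap_range", "gamma_range",
               "beta_thermo")) {
    if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
  }
  for (nm in c("height_mean", "height_sd", "fat_frac_mean", "fat_frac_sd")) {
    if (!is.null(y[[nm]])) {
      args[[nm]] <- c(male = y[[nm]]$male, female = y[[nm]]$female)
    }
  }
  do.call(pop_config, args)
}
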