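# Unit-safe identities linking K, dG, dH, dS and the van't Hoff
# heat-capacity fit. Boundary units follow calorimetric table convention:
# temperatures in degC, binding constants in mM^-1, energies in kcal/mol,
# entropies and heat capacities in cal mol^-1 K^-1.

KELVIN_OFFSET <- 273.15

as_kelvin <- function(temperature_C) temperature_C + KELVIN_OFFSET

#' Binding free energy from an association constant
#'
#' \eqn{\Delta G_b = -RT \ln K_b} with \eqn{K_b} referenced to the 1 M
#' standard state (the mM^-1 table unit is converted internally).
#'
#' @param Kb_mM Association constant, mM^-1 (vectorized).
#' @param temperature_C Temperature, degC.
#' @param constants An [energetic_constants()] object.
#' @return Free energy of binding, kcal mol^-1.
#' @examples
#' delta_g_from_k(64, 30) # -6.67 kcal/mol
#' @export
delta_g_from_k <- function(Kb_mM, temperature_C,
                           constants = energetic_constants()) {
  if (any(Kb_mM <= 0)) stop("Kb_mM must be positive")
  R_kcal <- constants$gas_constant / 1000
  -R_kcal * as_kelvin(temperature_C) * log(Kb_mM * 1000)
}

#' Entropic term of the Gibbs relation
#'
#' Returns \eqn{-T\Delta S_b = \Delta G_b - \Delta H_b}.
#'
#' @param dG_kcal,dH_kcal Free energy and enthalpy of binding, kcal mol^-1.
#' @return `-T dS`, kcal mol^-1.
#' @export
entropy_term <- function(dG_kcal, dH_kcal) dG_kcal - dH_kcal

#' Dissociation constant from the association constant
#'
#' @inheritParams delta_g_from_k
#' @return Dissociation constant, uM.
#' @examples
#' kd_from_kb(64) # 15.6 uM
#' @export
kd_from_kb <- function(Kb_mM) {
  if (any(Kb_mM <= 0)) stop("Kb_mM must be positive")
  1000 / Kb_mM
}

#' Binding entropy from the entropic term
#'
#' @param minus_TdS_kcal `-T dS` in kcal mol^-1.
#' @param temperature_C Temperature, degC.
#' @return `dS_b`, cal mol^-1 K^-1.
#' @export
ds_b_from_entropy_term <- function(minus_TdS_kcal, temperature_C) {
  -1000 * minus_TdS_kcal / as_kelvin(temperature_C)
}

#' Association constant implied by a free energy (inverse of delta_g_from_k)
#'
#' @param dG_kcal Free energy, kcal mol^-1.
#' @inheritParams delta_g_from_k
#' @return Association constant, mM^-1.
#' @export
k_from_delta_g <- function(dG_kcal, temperature_C,
                           constants = energetic_constants()) {
  R_kcal <- constants$gas_constant / 1000
  exp(-dG_kcal / (R_kcal * as_kelvin(temperature_C))) / 1000
}

#' One-row table of binding parameters
#'
#' Constructor for the per-complex, per-temperature parameter record used
#' across the package (and stored in the fitted-parameter CSV fixture).
#'
#' @param complex_label Text label of the complex.
#' @param temperature_C Temperature, degC (0-100).
#' @param n Stoichiometry (sites), dimensionless.
#' @param Kb_mM Association constant, mM^-1.
#' @param dH_kcal Binding enthalpy, kcal mol^-1.
#' @param Kb_err_mM,dH_err_kcal Fitted standard errors (optional).
#' @param ligand,mg_state Optional annotation columns.
#' @return A one-row tibble of class `binding_parameters`.
#' @export
binding_parameters <- function(complex_label, temperature_C, n = 1,
                               Kb_mM, dH_kcal,
                               Kb_err_mM = NA_real_, dH_err_kcal = NA_real_,
                               ligand = NA_character_,
                               mg_state = NA_character_) {
  stopifnot(
    "Kb_mM must be positive" = Kb_mM > 0,
    "n must be positive" = n > 0,
    "temperature_C must be in 0-100 degC" =
      temperature_C >= 0 && temperature_C <= 100
  )
  out <- tibble::tibble(
    complex_label = complex_label, ligand = ligand, mg_state = mg_state,
    temperature_C = temperature_C, n = n,
    Kb_mM = Kb_mM, Kb_err_mM = Kb_err_mM,
    dH_kcal = dH_kcal, dH_err_kcal = dH_err_kcal
  )
  class(out) <- c("binding_parameters", class(out))
  out
}

#' Derive state functions from binding parameters
#'
#' Adds the derived thermodynamic profile columns (`Kd_uM`, `dG_kcal`,
#' `minus_TdS_kcal`, `dS_cal`) to a table of measured binding parameters.
#' The Gibbs identity `dG = dH + (-T dS)` holds exactly by construction.
#'
#' @param data A data frame with columns `Kb_mM`, `dH_kcal`,
#'   `temperature_C` (e.g. from [binding_parameters()] or
#'   [read_binding_parameters()]).
#' @param constants An [energetic_constants()] object.
#' @return The input as a tibble with the four derived columns appended.
#' @examples
#' binding_parameters("EG", 30, Kb_mM = 64, dH_kcal = 1.07) |>
#'   derive_thermo()
#' @export
derive_thermo <- function(data, constants = energetic_constants()) {
  stopifnot(all(c("Kb_mM", "dH_kcal", "temperature_C") %in% names(data)))
  tibble::as_tibble(data) |>
    dplyr::mutate(
      Kd_uM = kd_from_kb(.data$Kb_mM),
      dG_kcal = delta_g_from_k(.data$Kb_mM, .data$temperature_C, constants),
      minus_TdS_kcal = entropy_term(.data$dG_kcal, .data$dH_kcal),
      dS_cal = ds_b_from_entropy_term(.data$minus_TdS_kcal,
                                      .data$temperature_C)
    )
}

#' van't Hoff heat-capacity fit
#'
#' Ordinary (unweighted) least-squares fit of the binding enthalpy against
#' temperature; the slope is the heat-capacity change of binding,
#' \eqn{\Delta C_p}, assumed constant over the temperature range spanned.
#' The fit is unweighted so that for three equally spaced points the slope
#' reduces to the two-point formula \eqn{(\Delta H_3-\Delta H_1)/(T_3-T_1)}.
#'
#' @param data A data frame with columns `temperature_C` (degC) and
#'   `dH_kcal` (kcal mol^-1), at two or more distinct temperatures.
#' @param Tref Reference temperature (degC) at which the fitted enthalpy
#'   is reported.
#' @return An object of class `cp_fit` with components `dCp_cal`,
#'   `dCp_err_cal` (slope and its standard error, cal mol^-1 K^-1),
#'   `dH_at_Tref_kcal`, `Tref_C`, `r_squared`, and the underlying `lm` fit.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @examples
#' tibble::tibble(temperature_C = c(25, 30, 35),
#'                dH_kcal = c(-6.6, -7.7, -9.1)) |>
#'   fit_delta_cp() # -250 cal/mol/K
#' @export
fit_delta_cp <- function(data, Tref = 25) {
  stopifnot(all(c("temperature_C", "dH_kcal") %in% names(data)))
  tt <- data$temperature_C
  if (length(unique(tt)) < 2) {
    stop("fit_delta_cp() needs dH at >= 2 distinct temperatures")
  }
  fit <- stats::lm(dH_kcal ~ temperature_C, data = data)
  # noise-free synthetic series fit exactly; summary.lm warns about it
  sm <- suppressWarnings(summary(fit))
  slope_kcal <- unname(stats::coef(fit)[2])
  slope_se <- if (nrow(data) > 2) unname(sm$coefficients[2, 2]) else NA_real_
  r2 <- if (nrow(data) > 2 || sm$sigma > 0) unname(sm$r.squared) else 1
  structure(
    list(
      dCp_cal = 1000 * slope_kcal,
      dCp_err_cal = 1000 * slope_se,
      dH_at_Tref_kcal = unname(stats::predict(
        fit, tibble::tibble(temperature_C = Tref))),
      Tref_C = Tref,
      r_squared = r2,
      n_points = nrow(data),
      fit = fit
    ),
    class = "cp_fit"
  )
}

#' @export
print.cp_fit <- function(x, ...) {
  cat(sprintf(
    "<cp_fit> dCp = %.4g cal/mol/K (se %.3g), dH(%g degC) = %.4g kcal/mol, R^2 = %.4f, n = %d\n",
    x$dCp_cal, x$dCp_err_cal, x$Tref_C, x$dH_at_Tref_kcal, x$r_squared,
    x$n_points))
  invisible(x)
}

#' Per-complex heat-capacity fits
#'
#' Groups a binding-parameter table by complex and fits [fit_delta_cp()]
#' to every complex measured at two or more temperatures; complexes with a
#' single temperature are dropped silently (no slope is defined).
#'
#' @param params Binding-parameter table with columns `complex_label`,
#'   `temperature_C`, `dH_kcal`.
#' @param Tref Passed to [fit_delta_cp()].
#' @return A tibble with one row per eligible complex: `complex_label`,
#'   `dCp_cal`, `dCp_err_cal`, `dH_at_Tref_kcal`, `r_squared`, `n_points`.
#' @export
fit_delta_cp_by <- function(params, Tref = 25) {
  stopifnot(all(c("complex_label", "temperature_C", "dH_kcal") %in%
                  names(params)))
  tibble::as_tibble(params) |>
    dplyr::group_by(.data$complex_label) |>
    dplyr::filter(dplyr::n_distinct(.data$temperature_C) >= 2) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_delta_cp(d, Tref = Tref)
      tibble::tibble(
        dCp_cal = f$dCp_cal, dCp_err_cal = f$dCp_err_cal,
        dH_at_Tref_kcal = f$dH_at_Tref_kcal,
        r_squared = f$r_squared, n_points = f$n_points
      )
    }) |>
    dplyr::ungroup()
}

#' Round half away from zero
#'
#' Presentation rounding used when reproducing printed tables (R's
#' `round()` rounds half to even). All internal arithmetic is unrounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
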