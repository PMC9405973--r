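# Deconvolution of the binding heat capacity and entropy into rigid-body,
# solvation and conformational contributions, with surface-area, residue
# and rotatable-bond equivalents.

#' Rigid-body heat-capacity change from buried surface area
#'
#' \eqn{\Delta C_{p,rb} = \alpha \Delta ASA_{ap} + \beta \Delta ASA_p}:
#' the heat-capacity change expected if binding buried only the interface
#' area, with no conformational rearrangement.
#'
#' @param dASA_ap,dASA_p Apolar and polar buried surface area, A^2
#'   (vectorized).
#' @param constants An [energetic_constants()] object.
#' @return Heat-capacity change, cal mol^-1 K^-1.
#' @export
cp_rigid_body <- function(dASA_ap, dASA_p,
                          constants = energetic_constants()) {
  constants$alpha * dASA_ap + constants$beta * dASA_p
}

#' Conformational heat-capacity change
#'
#' The part of the measured \eqn{\Delta C_{p,b}} not accounted for by the
#' rigid-body term: \eqn{\Delta C_{p,conf} = \Delta C_{p,b} - \Delta
#' C_{p,rb}}.
#'
#' @param dCp_b,dCp_rb Measured and rigid-body heat-capacity changes,
#'   cal mol^-1 K^-1.
#' @return Conformational heat-capacity change, cal mol^-1 K^-1.
#' @export
cp_conformational <- function(dCp_b, dCp_rb) dCp_b - dCp_rb

#' Hydrophobicity-weighted heat-capacity coefficient
#'
#' The per-A^2 coefficient for a surface of average interface
#' hydrophobicity: \eqn{\alpha f_{ap} + \beta (1 - f_{ap})} (0.2228 cal
#' K^-1 mol^-1 A^-2 with the defaults). The polar term carries weight
#' `1 - f_ap` so that the apolar and polar fractions sum to the whole
#' surface.
#'
#' @param constants An [energetic_constants()] object.
#' @return Coefficient, cal K^-1 mol^-1 A^-2.
#' @export
cp_conf_coefficient <- function(constants = energetic_constants()) {
  coef <- constants$alpha * constants$f_ap +
    constants$beta * (1 - constants$f_ap)
  if (coef <= 0) {
    stop("alpha*f_ap + beta*(1-f_ap) must be positive; check constants")
  }
  coef
}

#' Surface-area change implied by a conformational heat capacity
#'
#' Inverts the hydrophobicity-weighted parameterization:
#' `dASA_conf = dCp_conf / (alpha f_ap + beta (1 - f_ap))`. A negative
#' result corresponds to net exposure of surface.
#'
#' @param dCp_conf Conformational heat-capacity change, cal mol^-1 K^-1
#'   (vectorized).
#' @inheritParams cp_conf_coefficient
#' @return Conformational surface-area change, A^2.
#' @examples
#' asa_from_cp_conf(-222) # -996 A^2 (996 A^2 net change)
#' @export
asa_from_cp_conf <- function(dCp_conf,
                             constants = energetic_constants()) {
  dCp_conf / cp_conf_coefficient(constants)
}

#' Residue equivalent of a surface-area change
#'
#' @param dASA_conf Conformational surface-area change, A^2.
#' @inheritParams cp_conf_coefficient
#' @return `round(|dASA_conf| / asa_per_residue)` (half away from zero).
#' @export
n_residues_from_asa <- function(dASA_conf,
                                constants = energetic_constants()) {
  round_half_away(abs(dASA_conf) / constants$asa_per_residue)
}

#' Rotatable-bond equivalent of a conformational entropy
#'
#' @param dS_conf Conformational entropy change, cal mol^-1 K^-1.
#' @inheritParams cp_conf_coefficient
#' @return `round(|dS_conf| / dS_per_rotor)` (half away from zero).
#' @export
n_rotatable_bonds <- function(dS_conf,
                              constants = energetic_constants()) {
  round_half_away(abs(dS_conf) / constants$dS_per_rotor)
}

#' Heat-capacity decomposition
#'
#' Splits a measured binding heat capacity into rigid-body and
#' conformational parts and converts the conformational part into a
#' surface-area change and residue count. The closure
#' `dCp_b = dCp_rb + dCp_conf` holds exactly.
#'
#' @param data A data frame with columns `dCp_cal` (measured) and either
#'   `dCp_rb_cal` or both `dASA_ap` and `dASA_p`.
#' @param constants An [energetic_constants()] object.
#' @return The input with columns `dCp_rb_cal`, `dCp_conf_cal`,
#'   `dASA_conf` (A^2, negative = net exposure), `minus_dASA_conf` (the
#'   sign convention used in printed tables) and `n_conf_residues`
#'   appended.
#' @export
decompose_heat_capacity <- function(data,
                                    constants = energetic_constants()) {
  data <- tibble::as_tibble(data)
  stopifnot("dCp_cal" %in% names(data))
  if (!"dCp_rb_cal" %in% names(data)) {
    stopifnot(all(c("dASA_ap", "dASA_p") %in% names(data)))
    data$dCp_rb_cal <- cp_rigid_body(data$dASA_ap, data$dASA_p, constants)
  }
  data |>
    dplyr::mutate(
      dCp_conf_cal = cp_conformational(.data$dCp_cal, .data$dCp_rb_cal),
      dASA_conf = asa_from_cp_conf(.data$dCp_conf_cal, constants),
      minus_dASA_conf = -.data$dASA_conf,
      n_conf_residues = n_residues_from_asa(.data$dASA_conf, constants)
    )
}

#' Entropy decomposition
#'
#' Splits the binding entropy into solvation, roto-translational and
#' conformational parts:
#' \eqn{\Delta S_b = \Delta S_{solv} + \Delta S_{r-t} + \Delta S_{conf}},
#' with \eqn{\Delta S_{solv} = \Delta C_{p,b} \ln(T/T_s)}. The closure is
#' exact by construction.
#'
#' @param data A data frame with columns `minus_TdS_kcal`, `dCp_cal`,
#'   `temperature_C`.
#' @param constants An [energetic_constants()] object.
#' @return The input with `dS_cal`, `dS_solv_cal`, `dS_rt_cal`,
#'   `dS_conf_cal` (all cal mol^-1 K^-1) and `n_rot_bonds` appended.
#' @examples
#' tibble::tibble(minus_TdS_kcal = -2.20, dCp_cal = -270,
#'                temperature_C = 30) |>
#'   decompose_entropy() # dS_solv 64.7, dS_conf -49.4
#' @export
decompose_entropy <- function(data, constants = energetic_constants()) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("minus_TdS_kcal", "dCp_cal", "temperature_C") %in%
                  names(data)))
  data |>
    dplyr::mutate(
      dS_cal = ds_b_from_entropy_term(.data$minus_TdS_kcal,
                                      .data$temperature_C),
      dS_solv_cal = .data$dCp_cal *
        log(as_kelvin(.data$temperature_C) / constants$Ts),
      dS_rt_cal = constants$dS_rt,
      dS_conf_cal = .data$dS_cal - .data$dS_solv_cal - .data$dS_rt_cal,
      n_rot_bonds = n_rotatable_bonds(.data$dS_conf_cal, constants)
    )
}

#' Full structural-energetic table
#'
#' Builds the complete deconvolution table (one row per complex at the
#' analysis temperature): measured `dCp_b` from the per-complex van't
#' Hoff fits, rigid-body `dCp_rb` looked up per (ligand, mg_state), the
#' conformational split with surface-area/residue equivalents, and the
#' entropy split with rotatable-bond equivalents.
#'
#' @param params Binding-parameter table (all temperatures; the entropy
#'   term is taken at `temperature_C`).
#' @param dcp_rb Rigid-body lookup: columns `ligand`, `mg_state`,
#'   `dCp_rb_cal`.
#' @param constants An [energetic_constants()] object.
#' @param temperature_C Analysis temperature (degC).
#' @param cp_fits Optional precomputed [fit_delta_cp_by()] table; fitted
#'   from `params` when omitted.
#' @return A tibble with one row per complex having both a heat-capacity
#'   fit and a rigid-body value; complexes lacking either are dropped.
#' @export
structural_energetics_table <- function(params, dcp_rb,
                                        constants = energetic_constants(),
                                        temperature_C = 30,
                                        cp_fits = NULL) {
  params <- tibble::as_tibble(params)
  if (is.null(cp_fits)) cp_fits <- fit_delta_cp_by(params)
  at_T <- params |>
    dplyr::filter(.data$temperature_C == !!temperature_C) |>
    derive_thermo(constants)
  at_T |>
    dplyr::inner_join(
      dplyr::select(cp_fits, "complex_label", "dCp_cal"),
      by = "complex_label") |>
    dplyr::inner_join(tibble::as_tibble(dcp_rb),
                      by = c("ligand", "mg_state")) |>
    decompose_heat_capacity(constants) |>
    decompose_entropy(constants) |>
    dplyr::select(
      "complex_label", "ligand", "mg_state", "temperature_C",
      "dCp_cal", "dCp_rb_cal", "dCp_conf_cal",
      "dASA_conf", "minus_dASA_conf", "n_conf_residues",
      "dS_cal", "dS_solv_cal", "dS_rt_cal", "dS_conf_cal", "n_rot_bonds"
    )
}
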