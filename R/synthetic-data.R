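# Generator of synthetic ITC experiments with known ground truth: the
# forward model plus i.i.d. Gaussian noise on the raw injection heats
# (instrument noise arises in per-injection power integration, so it is
# applied in ucal, not on normalized heats) and an optional constant
# blank offset. All randomness flows from the single seed in the spec.

#' Specification of a synthetic ITC experiment
#'
#' @param truth Ground-truth parameters: for `mode = "one_site"` a list
#'   with `n`, `Kb_mM`, `dH_kcal`; for `mode = "ternary"` a list with
#'   `n`, `K_EG`, `K_EMG` (M^-1), `dH_EG_kcal`, `dH_EMG_kcal`.
#' @param protocol A [titration_protocol()]. The default mirrors the
#'   emulated experiments: 200 uL cell, 19 x 2 uL injections, 40 uM
#'   protein, 2.5 mM ligand.
#' @param noise_sd_ucal Gaussian noise standard deviation per injection,
#'   ucal.
#' @param blank_offset_ucal Constant dilution-heat offset, ucal.
#' @param seed Integer seed fixing the full output stream.
#' @param mode `"one_site"` or `"ternary"`.
#' @param mg_constants [mg_constants()] (required for ternary mode).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(truth,
                           protocol = titration_protocol(),
                           noise_sd_ucal = 0.05,
                           blank_offset_ucal = 0,
                           seed = 1L,
                           mode = c("one_site", "ternary"),
                           mg_constants = NULL) {
  mode <- match.arg(mode)
  stopifnot(
    "noise_sd_ucal must be >= 0" = noise_sd_ucal >= 0,
    "seed must be a single finite number" =
      length(seed) == 1 && is.finite(seed)
  )
  structure(
    list(truth = as.list(truth), protocol = protocol,
         noise_sd_ucal = noise_sd_ucal,
         blank_offset_ucal = blank_offset_ucal,
         seed = as.integer(seed), mode = mode,
         mg_constants = mg_constants),
    class = "generator_spec"
  )
}

#' Generate one synthetic isotherm (sample plus blank)
#'
#' `sample = forward-model heats + noise + blank_offset`;
#' `blank = blank_offset + independent noise`. Byte-identical output is
#' reproduced by re-running with the same spec (same seed).
#'
#' @param spec A [generator_spec()].
#' @return A list with `sample` and `blank` (`itc_isotherm` tibbles) and
#'   `truth` (the ground-truth list).
#' @export
generate_isotherm <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  clean <- predict_injection_heats(spec$protocol, spec$truth,
                                   mode = spec$mode,
                                   mg_constants = spec$mg_constants)
  n_inj <- nrow(clean)
  noise <- withr::with_seed(spec$seed, stats::rnorm(2 * n_inj))
  sample_q <- clean$Q_ucal + spec$blank_offset_ucal +
    spec$noise_sd_ucal * noise[seq_len(n_inj)]
  blank_q <- spec$blank_offset_ucal +
    spec$noise_sd_ucal * noise[n_inj + seq_len(n_inj)]
  renorm <- function(q_ucal) {
    dv_L <- clean$inj_volume_uL * 1e-6
    L_syr <- spec$protocol$syringe_mM * 1e-3
    if (L_syr > 0) (q_ucal * 1e-9) / (dv_L * L_syr) else rep(0, n_inj)
  }
  sample <- clean
  sample$Q_ucal <- sample_q
  sample$ndh_kcal_per_mol <- renorm(sample_q)
  blank <- clean
  blank$Q_ucal <- blank_q
  blank$ndh_kcal_per_mol <- renorm(blank_q)
  list(
    sample = new_isotherm(sample, protocol = spec$protocol),
    blank = new_isotherm(blank, protocol = spec$protocol),
    truth = spec$truth
  )
}

#' Generate a temperature series with a known heat capacity
#'
#' Propagates one-site ground truth across temperatures assuming a
#' constant heat capacity: `dH(T) = dH(T0) + dCp (T - T0)` and the
#' integrated van't Hoff relation for `K(T)`,
#' \deqn{\ln K(T) = \ln K(T_0) + \frac{\Delta H_0 - \Delta C_p
#'   T_0}{R}\left(\frac{1}{T_0}-\frac{1}{T}\right) + \frac{\Delta
#'   C_p}{R}\ln\frac{T}{T_0}.}
#'
#' @param truth_at_ref One-site truth (`n`, `Kb_mM`, `dH_kcal`) at
#'   `ref_temperature_C`.
#' @param dCp_true_cal Heat-capacity change, cal mol^-1 K^-1.
#' @param temps_C Temperatures to generate, degC (>= 2).
#' @param spec Template [generator_spec()] supplying protocol, noise and
#'   base seed; per-temperature seeds are `seed + index - 1`.
#' @param ref_temperature_C Reference temperature of the truth, degC.
#' @param constants An [energetic_constants()] object (gas constant).
#' @return A list of [generator_spec()]s, one per temperature, each with
#'   the temperature-propagated truth and matching protocol temperature.
#' @export
generate_temperature_series <- function(truth_at_ref, dCp_true_cal,
                                        temps_C, spec,
                                        ref_temperature_C = 25,
                                        constants = energetic_constants()) {
  if (length(temps_C) < 2) stop("need >= 2 temperatures")
  truth_at_ref <- as.list(truth_at_ref)
  R_kcal <- constants$gas_constant / 1000
  dCp_kcal <- dCp_true_cal / 1000
  T0 <- as_kelvin(ref_temperature_C)
  lapply(seq_along(temps_C), function(i) {
    Tk <- as_kelvin(temps_C[i])
    dH_T <- truth_at_ref$dH_kcal + dCp_kcal * (Tk - T0)
    lnK_T <- log(truth_at_ref$Kb_mM * 1000) +
      (truth_at_ref$dH_kcal - dCp_kcal * T0) / R_kcal * (1 / T0 - 1 / Tk) +
      dCp_kcal / R_kcal * log(Tk / T0)
    proto <- spec$protocol
    proto$temperature_C <- temps_C[i]
    generator_spec(
      truth = list(n = truth_at_ref$n, Kb_mM = exp(lnK_T) / 1000,
                   dH_kcal = dH_T),
      protocol = proto,
      noise_sd_ucal = spec$noise_sd_ucal,
      blank_offset_ucal = spec$blank_offset_ucal,
      seed = spec$seed + i - 1L,
      mode = "one_site"
    )
  })
}

#' Generate a paired +/-Mg experiment from ternary ground truth
#'
#' Two experiments sharing the protein truth, one at each Mg level,
#' suitable for [fit_ternary()].
#'
#' @param ternary_truth List with `n`, `K_EG`, `K_EMG`, `dH_EG_kcal`,
#'   `dH_EMG_kcal`.
#' @param mg_constants An [mg_constants()] object.
#' @param spec Template [generator_spec()] (protocol, noise, seed).
#' @param mg_levels_mM Total Mg of the two experiments, mM (default the
#'   emulated 0 and 5 mM conditions).
#' @return A named list of two [generator_spec()]s, `nomg` and `mg`.
#' @export
generate_coupled_pair <- function(ternary_truth, mg_constants, spec,
                                  mg_levels_mM = c(0, 5)) {
  stopifnot(length(mg_levels_mM) == 2)
  out <- lapply(seq_along(mg_levels_mM), function(i) {
    proto <- spec$protocol
    proto$total_Mg_mM <- mg_levels_mM[i]
    generator_spec(
      truth = ternary_truth, protocol = proto,
      noise_sd_ucal = spec$noise_sd_ucal,
      blank_offset_ucal = spec$blank_offset_ucal,
      seed = spec$seed + i - 1L,
      mode = "ternary", mg_constants = mg_constants
    )
  })
  names(out) <- ifelse(mg_levels_mM == 0, "nomg", "mg")
  out
}

#' Write the ground truth of a generator spec as a JSON sidecar
#'
#' @param spec A [generator_spec()].
#' @param path Output path.
#' @export
write_truth_json <- function(spec, path) {
  stopifnot(inherits(spec, "generator_spec"))
  jsonlite::write_json(
    list(truth = spec$truth, mode = spec$mode,
         noise_sd_ucal = spec$noise_sd_ucal,
         blank_offset_ucal = spec$blank_offset_ucal,
         seed = spec$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
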