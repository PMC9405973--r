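# Heterotropic cooperativity: how the binding of one ligand (Mg2+, Sdo1)
# changes the association of another. kappa = K_num / K_den at equal
# temperature; dg = -RT ln kappa; dh = dH_num - dH_den; -Tds = dg - dh.

#' Heterotropic cooperativity cycle edge
#'
#' Computes the cooperativity parameters for one heterotropic effect:
#' the ratio of association constants of a ligand in the presence versus
#' absence of a second ligand, and the corresponding free-energy,
#' enthalpy and entropy couplings.
#'
#' @param params_num,params_den One-row [binding_parameters()] (or lists
#'   with `Kb_mM`, `dH_kcal`, `temperature_C`, `complex_label`) for the
#'   numerator and denominator complexes; temperatures must match.
#' @param constants An [energetic_constants()] object.
#' @param effect_label Optional label describing the effect.
#' @return A one-row tibble of class `coop_cycle` with columns
#'   `effect_label`, `numerator_complex`, `denominator_complex`,
#'   `temperature_C`, `kappa`, `dg_kcal`, `dh_kcal`, `minus_Tds_kcal`.
#'   The identities `dg = -RT ln(kappa)` and `-Tds = dg - dh` hold
#'   exactly.
#' @examples
#' num <- binding_parameters("E.MgGTP", 30, Kb_mM = 64, dH_kcal = 1.07)
#' den <- binding_parameters("E.GTP", 30, Kb_mM = 156, dH_kcal = 1.7)
#' heterotropic_cycle(num, den) # kappa 0.41, dh -0.63
#' @export
heterotropic_cycle <- function(params_num, params_den,
                               constants = energetic_constants(),
                               effect_label = NA_character_) {
  num <- as.list(params_num)
  den <- as.list(params_den)
  if (!isTRUE(all.equal(num$temperature_C, den$temperature_C))) {
    stop("numerator and denominator temperatures differ")
  }
  if (num$Kb_mM <= 0 || den$Kb_mM <= 0) stop("Kb must be positive")
  R_kcal <- constants$gas_constant / 1000
  Tk <- as_kelvin(num$temperature_C)
  kappa <- num$Kb_mM / den$Kb_mM
  dg <- -R_kcal * Tk * log(kappa)
  dh <- num$dH_kcal - den$dH_kcal
  out <- tibble::tibble(
    effect_label = effect_label,
    numerator_complex = num$complex_label %||% NA_character_,
    denominator_complex = den$complex_label %||% NA_character_,
    temperature_C = num$temperature_C,
    kappa = kappa, dg_kcal = dg, dh_kcal = dh,
    minus_Tds_kcal = dg - dh
  )
  class(out) <- c("coop_cycle", class(out))
  out
}

#' Cooperativity table from a cycle specification
#'
#' Joins a cycle specification (effect label plus numerator and
#' denominator complex labels) against a binding-parameter table and
#' computes one [heterotropic_cycle()] row per effect per shared
#' temperature.
#'
#' @param params Binding-parameter table (columns `complex_label`,
#'   `temperature_C`, `Kb_mM`, `dH_kcal`).
#' @param cycles Cycle specification: columns `effect_label`,
#'   `numerator_complex`, `denominator_complex` (see
#'   [read_cycle_spec()]).
#' @param constants An [energetic_constants()] object.
#' @return A tibble of cooperativity rows; effects whose complexes are
#'   missing from `params` are dropped with a warning naming them.
#' @export
cooperativity_table <- function(params, cycles,
                                constants = energetic_constants()) {
  params <- tibble::as_tibble(params)
  cycles <- tibble::as_tibble(cycles)
  missing <- setdiff(
    unique(c(cycles$numerator_complex, cycles$denominator_complex)),
    params$complex_label
  )
  if (length(missing) > 0) {
    warning("cycle complexes missing from parameter table: ",
            paste(missing, collapse = ", "))
  }
  purrr::pmap_dfr(cycles, function(effect_label, numerator_complex,
                                   denominator_complex, ...) {
    num <- dplyr::filter(params, .data$complex_label == numerator_complex)
    den <- dplyr::filter(params, .data$complex_label == denominator_complex)
    temps <- intersect(num$temperature_C, den$temperature_C)
    purrr::map_dfr(temps, function(tt) {
      heterotropic_cycle(
        dplyr::filter(num, .data$temperature_C == tt)[1, ],
        dplyr::filter(den, .data$temperature_C == tt)[1, ],
        constants = constants, effect_label = effect_label
      )
    })
  })
}

#' Read a cycle-specification CSV
#'
#' @param path CSV with columns `effect_label`, `numerator_complex`,
#'   `denominator_complex` (comment lines start with `#`).
#' @return A tibble.
#' @export
read_cycle_spec <- function(path) {
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("effect_label", "numerator_complex",
                  "denominator_complex") %in% names(d)))
  d
}

#' Thermodynamic-cycle closure check
#'
#' A heterotropic square connects four binding steps between the same end
#' states: X binding the free receptor (`x_to_e`), X binding the
#' receptor-S complex (`x_to_es`), S binding the free receptor
#' (`s_to_e`), and S binding the receptor-X complex (`s_to_ex`). Detailed
#' balance requires the two paths to agree:
#' `K(x_to_e) * K(s_to_ex) = K(s_to_e) * K(x_to_es)` and the analogous
#' enthalpy path sums. Equivalently, the cooperativity of X on S equals
#' that of S on X (kappa reciprocity).
#'
#' @param edges A data frame with one row per edge: columns `edge` (one
#'   each of `"x_to_e"`, `"x_to_es"`, `"s_to_e"`, `"s_to_ex"`), `Kb_mM`,
#'   `dH_kcal`, and `temperature_C` (all equal).
#' @param tolerance Flagging threshold on the absolute ln-K discrepancy
#'   (default 0.2 ln-units, commensurate with 10-30% experimental K
#'   errors).
#' @param dh_tolerance Flagging threshold on the enthalpy path-sum
#'   discrepancy, kcal mol^-1.
#' @return A one-row tibble: `ln_K_discrepancy` (ln of the path-product
#'   ratio), `kappa_xy`, `kappa_yx` (the two reciprocal cooperativities),
#'   `dh_discrepancy_kcal`, and logical `consistent`.
#' @export
cycle_closure_check <- function(edges, tolerance = 0.2,
                                dh_tolerance = 1) {
  edges <- tibble::as_tibble(edges)
  need <- c("x_to_e", "x_to_es", "s_to_e", "s_to_ex")
  if (!setequal(edges$edge, need) || nrow(edges) != 4) {
    stop("edges must contain exactly one row for each of: ",
         paste(need, collapse = ", "))
  }
  if (length(unique(edges$temperature_C)) != 1) {
    stop("all four edges must share the temperature")
  }
  k <- function(e) edges$Kb_mM[edges$edge == e]
  h <- function(e) edges$dH_kcal[edges$edge == e]
  if (any(edges$Kb_mM <= 0)) stop("all K must be positive")
  ln_disc <- log((k("x_to_e") * k("s_to_ex")) /
                   (k("s_to_e") * k("x_to_es")))
  dh_disc <- (h("x_to_e") + h("s_to_ex")) - (h("s_to_e") + h("x_to_es"))
  tibble::tibble(
    temperature_C = edges$temperature_C[1],
    kappa_xy = k("x_to_es") / k("x_to_e"), # effect of S on X binding
    kappa_yx = k("s_to_ex") / k("s_to_e"), # effect of X on S binding
    ln_K_discrepancy = ln_disc,
    dh_discrepancy_kcal = dh_disc,
    consistent = abs(ln_disc) <= tolerance &
      abs(dh_disc) <= dh_tolerance
  )
}
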