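# End-to-end driver: read the fitted-parameter table, constants,
# rigid-body lookup and cycle specification; compute every derived
# column (state functions, heat capacities, cooperativity cycles, the
# structural-energetic deconvolution); optionally compare against a
# reference transcription and write CSV/markdown outputs.

#' Read a fitted-parameter CSV
#'
#' Columns: `complex_label`, `ligand`, `mg_state`, `temperature_C`, `n`,
#' `Kb_mM`, `Kb_err_mM`, `dH_kcal`, `dH_err_kcal`, and optionally
#' `source`. Comment lines start with `#`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_binding_parameters <- function(path) {
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("complex_label", "temperature_C", "Kb_mM", "dH_kcal")
  stopifnot(all(need %in% names(d)))
  if (!"n" %in% names(d)) d$n <- 1
  d
}

#' Paths to the packaged example data
#'
#' The package ships a plain-text transcription of the measured columns
#' (association constants and binding enthalpies per complex per
#' temperature) of the published Efl1 R1086Q calorimetric study, along
#' with the cycle specification, the per-ligand rigid-body heat
#' capacities, a constants file, and reference transcriptions of the
#' published derived tables for comparison.
#'
#' @param file File name within the package's `extdata`; `NULL` lists
#'   the available files.
#' @return A file path (or a character vector of file names).
#' @export
itc_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "itcthermo"))
  } else {
    p <- system.file("extdata", file, package = "itcthermo")
    if (p == "") stop("no packaged file called ", file)
    p
  }
}

#' Load the packaged Efl1 R1086Q fixture set
#'
#' @return A list with `params`, `cycles`, `dcp_rb` (tibbles),
#'   `constants` (an [energetic_constants()]), and `reference` (a list of
#'   tibbles `binding`, `cooperativity`, `structural` transcribing the
#'   published derived values).
#' @export
load_efl1_fixtures <- function() {
  rd <- function(f) readr::read_csv(itc_example(f), comment = "#",
                                    show_col_types = FALSE)
  list(
    params = read_binding_parameters(itc_example("efl1_binding_parameters.csv")),
    cycles = read_cycle_spec(itc_example("cooperativity_cycles.csv")),
    dcp_rb = rd("dcp_rigid_body.csv"),
    constants = read_constants(itc_example("constants.toml")),
    reference = list(
      binding = rd("reference_binding.csv"),
      cooperativity = rd("reference_cooperativity.csv"),
      structural = rd("reference_structural.csv")
    )
  )
}

#' Recompute every derived table from measured binding parameters
#'
#' From the measured columns (K_b, dH per complex per temperature) and
#' the constants, computes: the state-function table (dG, -TdS, K_d per
#' row), the per-complex van't Hoff heat capacities, the heterotropic
#' cooperativity table, and the structural-energetic deconvolution at
#' the analysis temperature. Rows referenced by the cycle specification
#' but missing from the parameter table are reported and skipped; an
#' empty parameter table yields empty outputs with a warning.
#'
#' @param params Binding-parameter table (tibble or CSV path).
#' @param cycles Cycle specification (tibble or CSV path), or `NULL` to
#'   skip the cooperativity table.
#' @param dcp_rb Rigid-body heat-capacity lookup (tibble or CSV path),
#'   or `NULL` to skip the structural table.
#' @param constants An [energetic_constants()] object or constants-file
#'   path.
#' @param reference Optional list of reference transcriptions (tibbles)
#'   with elements `binding`, `cooperativity`, `structural`; when given,
#'   a per-cell comparison report is included.
#' @param temperature_C Analysis temperature for the structural table.
#' @param out_dir Optional output directory: one CSV per table plus a
#'   markdown summary are written there.
#' @param round Also include presentation-rounded copies (half away from
#'   zero at table precision) in the output list.
#' @return A list of class `itc_tables` with elements `binding`,
#'   `heat_capacity`, `cooperativity`, `structural`, `comparison` (or
#'   `NULL`), and `presented` when `round = TRUE`.
#' @export
reproduce_tables <- function(params,
                             cycles = NULL,
                             dcp_rb = NULL,
                             constants = energetic_constants(),
                             reference = NULL,
                             temperature_C = 30,
                             out_dir = NULL,
                             round = TRUE) {
  if (is.character(params)) params <- read_binding_parameters(params)
  if (is.character(cycles)) cycles <- read_cycle_spec(cycles)
  if (is.character(dcp_rb)) {
    dcp_rb <- readr::read_csv(dcp_rb, comment = "#", show_col_types = FALSE)
  }
  if (is.character(constants)) constants <- read_constants(constants)
  params <- tibble::as_tibble(params)

  if (nrow(params) == 0) {
    warning("empty parameter table: producing empty outputs")
    out <- structure(
      list(binding = params, heat_capacity = tibble::tibble(),
           cooperativity = tibble::tibble(), structural = tibble::tibble(),
           comparison = NULL),
      class = "itc_tables")
    return(out)
  }

  binding <- derive_thermo(params, constants)
  heat_capacity <- fit_delta_cp_by(params)
  binding <- dplyr::left_join(
    binding,
    dplyr::select(heat_capacity, "complex_label", "dCp_cal", "dCp_err_cal"),
    by = "complex_label")

  cooperativity <- if (!is.null(cycles)) {
    cooperativity_table(params, cycles, constants)
  } else {
    tibble::tibble()
  }

  structural <- if (!is.null(dcp_rb)) {
    structural_energetics_table(params, dcp_rb, constants,
                                temperature_C = temperature_C)
  } else {
    tibble::tibble()
  }

  comparison <- if (!is.null(reference)) {
    compare_to_reference(binding, cooperativity, structural, reference,
                         constants = constants)
  } else {
    NULL
  }

  out <- structure(
    list(binding = binding, heat_capacity = heat_capacity,
         cooperativity = cooperativity, structural = structural,
         comparison = comparison),
    class = "itc_tables")

  if (round) out$presented <- present_tables(out)
  if (!is.null(out_dir)) write_itc_tables(out, out_dir)
  out
}

#' @export
print.itc_tables <- function(x, ...) {
  cat(sprintf(
    "<itc_tables> binding %d rows, heat_capacity %d, cooperativity %d, structural %d%s\n",
    nrow(x$binding), nrow(x$heat_capacity), nrow(x$cooperativity),
    nrow(x$structural),
    if (!is.null(x$comparison)) {
      sprintf("; comparison: %d/%d cells within tolerance",
              sum(x$comparison$within_tolerance),
              nrow(x$comparison))
    } else ""))
  invisible(x)
}

#' Presentation rounding of the derived tables
#'
#' Rounds (half away from zero) to typical printed table precision; all
#' internal computation elsewhere is unrounded.
#'
#' @param tables An `itc_tables` list.
#' @return A list of rounded tibbles.
#' @export
present_tables <- function(tables) {
  r <- round_half_away
  binding <- tables$binding |>
    dplyr::mutate(
      Kd_uM = r(.data$Kd_uM, 1), dG_kcal = r(.data$dG_kcal, 2),
      minus_TdS_kcal = r(.data$minus_TdS_kcal, 2),
      dS_cal = r(.data$dS_cal, 1),
      dCp_cal = r(.data$dCp_cal, 0))
  cooperativity <- if (nrow(tables$cooperativity) > 0) {
    tables$cooperativity |>
      dplyr::mutate(
        kappa = r(.data$kappa, 1), dg_kcal = r(.data$dg_kcal, 1),
        dh_kcal = r(.data$dh_kcal, 1),
        minus_Tds_kcal = r(.data$minus_Tds_kcal, 1))
  } else {
    tables$cooperativity
  }
  structural <- if (nrow(tables$structural) > 0) {
    tables$structural |>
      dplyr::mutate(dplyr::across(
        c("dCp_cal", "dCp_rb_cal", "dCp_conf_cal", "dASA_conf",
          "minus_dASA_conf", "dS_cal", "dS_solv_cal", "dS_rt_cal",
          "dS_conf_cal"),
        ~ r(.x, 0)))
  } else {
    tables$structural
  }
  list(binding = binding, cooperativity = cooperativity,
       structural = structural)
}

# ---- comparison against a reference transcription ----------------------

# Tolerance convention: printed-value cells carry `*_dp` decimal-place
# columns in the reference files; the tolerance for a derived cell is one
# unit of its last printed digit, except that quantities formed as the
# difference of two independently rounded enthalpic terms (-TdS, dh,
# -Tds) get 1.5 units, heat capacities get max(one unit, the printed
# standard error), and residue/rotor counts are compared after rounding
# with a +/-1 allowance.

compare_cells <- function(computed, reference, keys, quantities, table) {
  joined <- dplyr::inner_join(computed, reference, by = keys,
                              suffix = c("_calc", "_ref"))
  purrr::map_dfr(names(quantities), function(q) {
    calc_col <- if (paste0(q, "_calc") %in% names(joined)) {
      paste0(q, "_calc")
    } else {
      q
    }
    ref_col <- paste0(q, "_ref")
    if (!ref_col %in% names(joined)) return(tibble::tibble())
    tol <- quantities[[q]](joined)
    calc <- joined[[calc_col]]
    ref <- joined[[ref_col]]
    tibble::tibble(
      table = table,
      joined[keys],
      quantity = q,
      computed = calc,
      reference = ref,
      tolerance = tol,
      deviation = calc - ref,
      within_tolerance = is.na(ref) | abs(calc - ref) <= tol + 1e-9
    ) |>
      dplyr::filter(!is.na(ref))
  })
}

dp_tol <- function(col, factor = 1) {
  function(d) factor * 10^(-d[[col]])
}

#' Compare derived tables with a reference transcription
#'
#' Tolerances follow the printed precision of each reference cell, with
#' rounding of the measured inputs propagated: one unit of the last
#' printed digit for cells that depend only on K (K_d, dG, kappa, dg);
#' 1.5 units for differences of two independently rounded enthalpic
#' terms (-TdS, dh, -Tds); for heat capacities, the larger of one unit
#' and the printed standard error of the fit (printed dH values are
#' rounded to 0.1 kcal, which alone moves a 10-K slope by up to 10
#' cal/mol/K); and for the structural cells downstream of the fitted
#' dCp, one unit plus that dCp allowance propagated through the
#' decomposition algebra. Counts are compared after rounding, +/-1.
#'
#' @param binding,cooperativity,structural Derived tables from
#'   [reproduce_tables()].
#' @param reference List of reference tibbles (see
#'   [load_efl1_fixtures()]); each carries `*_dp` columns giving the
#'   printed decimal places.
#' @param constants The [energetic_constants()] used for the derivation.
#' @return A long tibble with one row per compared cell: `table`, key
#'   columns, `quantity`, `computed`, `reference`, `tolerance`,
#'   `deviation`, `within_tolerance`.
#' @export
compare_to_reference <- function(binding, cooperativity, structural,
                                 reference,
                                 constants = energetic_constants()) {
  out <- list()
  if (!is.null(reference$binding) && nrow(binding) > 0) {
    ref <- reference$binding
    out$binding <- compare_cells(
      binding, ref, keys = c("complex_label", "temperature_C"),
      quantities = list(
        Kd_uM = dp_tol("Kd_dp"),
        dG_kcal = dp_tol("dG_dp"),
        minus_TdS_kcal = dp_tol("mTdS_dp", 1.5),
        dCp_cal = function(d) pmax(1, d$dCp_err_cal_ref, na.rm = TRUE)
      ),
      table = "binding")
  }
  if (!is.null(reference$cooperativity) && nrow(cooperativity) > 0) {
    out$cooperativity <- compare_cells(
      cooperativity, reference$cooperativity,
      keys = c("effect_label", "temperature_C"),
      quantities = list(
        kappa = dp_tol("kappa_dp"),
        dg_kcal = dp_tol("dg_dp"),
        dh_kcal = dp_tol("dh_dp", 1.5),
        minus_Tds_kcal = dp_tol("mTds_dp", 1.5)
      ),
      table = "cooperativity")
  }
  if (!is.null(reference$structural) && nrow(structural) > 0) {
    coef <- cp_conf_coefficient(constants)
    tol_dcp <- function(d) pmax(1, d$dCp_err_cal, na.rm = TRUE)
    lnT <- function(d) abs(log(as_kelvin(d$temperature_C) / constants$Ts))
    count_cmp <- structural |>
      dplyr::mutate(
        n_conf_residues = round_half_away(.data$n_conf_residues),
        n_rot_bonds = round_half_away(.data$n_rot_bonds))
    out$structural <- compare_cells(
      count_cmp, reference$structural, keys = "complex_label",
      quantities = list(
        dCp_conf_cal = function(d) 1 + tol_dcp(d),
        minus_dASA_conf = function(d) 1 + tol_dcp(d) / coef,
        n_conf_residues = function(d)
          1 + tol_dcp(d) / (coef * constants$asa_per_residue),
        dS_cal = function(d) rep(1, nrow(d)),
        dS_solv_cal = function(d) 1 + tol_dcp(d) * lnT(d),
        dS_conf_cal = function(d) 1 + tol_dcp(d) * lnT(d),
        n_rot_bonds = function(d)
          1 + tol_dcp(d) * lnT(d) / constants$dS_per_rotor
      ),
      table = "structural")
  }
  dplyr::bind_rows(out)
}

#' Write the derived tables to disk
#'
#' One CSV per table plus a short markdown summary; a run manifest is
#' logged to stderr for reproducibility.
#'
#' @param tables An `itc_tables` list.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_itc_tables <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("binding", "heat_capacity", "cooperativity", "structural")) {
    if (nrow(tables[[nm]]) > 0) {
      readr::write_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  if (!is.null(tables$comparison)) {
    readr::write_csv(tables$comparison,
                     file.path(out_dir, "comparison.csv"))
  }
  md <- c(
    "# Derived thermodynamic tables", "",
    sprintf("- binding rows: %d", nrow(tables$binding)),
    sprintf("- heat-capacity fits: %d", nrow(tables$heat_capacity)),
    sprintf("- cooperativity rows: %d", nrow(tables$cooperativity)),
    sprintf("- structural rows: %d", nrow(tables$structural)),
    if (!is.null(tables$comparison)) {
      sprintf("- comparison: %d/%d cells within tolerance",
              sum(tables$comparison$within_tolerance),
              nrow(tables$comparison))
    }
  )
  writeLines(md, file.path(out_dir, "summary.md"))
  message(sprintf("wrote %d tables to %s", 4, out_dir))
  invisible(out_dir)
}

#' Run the synthetic generator-fit-derive chain
#'
#' Executes, at fixed seeds derived from `seed`: (1) one-site parameter
#' recovery over noisy replicates, (2) a noise-free temperature series
#' recovering the heat capacity, (3) a noise-free ternary round trip.
#' Summarises recovery per parameter.
#'
#' @param seed Base seed.
#' @param n_replicates Number of noisy one-site replicates.
#' @param noise_sd_ucal Injection noise, ucal.
#' @param out_dir Optional directory for a CSV recovery report.
#' @return A tibble with one row per (experiment, parameter): truth,
#'   median estimate, median relative error.
#' @export
run_synthetic_suite <- function(seed = 42, n_replicates = 20,
                                noise_sd_ucal = 0.05, out_dir = NULL) {
  truth <- list(n = 1, Kb_mM = 64, dH_kcal = 1.07)
  proto <- titration_protocol()

  fits <- purrr::map(seq_len(n_replicates), function(i) {
    sp <- generator_spec(truth, proto, noise_sd_ucal = noise_sd_ucal,
                         seed = seed + i - 1L)
    g <- generate_isotherm(sp)
    f <- fit_one_site(subtract_dilution(g$sample, g$blank), proto)
    stats::setNames(f$estimates$estimate, f$estimates$term)
  })
  one_site <- purrr::map_dfr(c("n", "Kb_mM", "dH_kcal"), function(term) {
    est <- vapply(fits, `[[`, numeric(1), term)
    tv <- truth[[term]]
    tibble::tibble(experiment = "one_site_noisy", parameter = term,
                   truth = tv, median_estimate = stats::median(est),
                   median_rel_error = stats::median(abs(est - tv) / abs(tv)))
  })

  base_spec <- generator_spec(truth, proto, noise_sd_ucal = 0, seed = seed)
  series <- generate_temperature_series(truth, dCp_true_cal = -250,
                                        temps_C = c(25, 30, 35),
                                        spec = base_spec)
  dh_hat <- purrr::map_dfr(series, function(sp) {
    g <- generate_isotherm(sp)
    f <- fit_one_site(g$sample, sp$protocol)
    tibble::tibble(temperature_C = sp$protocol$temperature_C,
                   dH_kcal = f$estimates$estimate[
                     f$estimates$term == "dH_kcal"])
  })
  cp <- fit_delta_cp(dh_hat)
  vant_hoff <- tibble::tibble(
    experiment = "temperature_series_noise_free", parameter = "dCp_cal",
    truth = -250, median_estimate = cp$dCp_cal,
    median_rel_error = abs(cp$dCp_cal + 250) / 250)

  ternary_truth <- list(n = 1, K_EG = 1.56e5, K_EMG = 6.4e4,
                        dH_EG_kcal = 1.7, dH_EMG_kcal = 1.07)
  mgc <- mg_constants(K_MgG = 1e4, K_Mg2G = 0)
  pair <- generate_coupled_pair(
    ternary_truth, mgc,
    generator_spec(truth, proto, noise_sd_ucal = 0, seed = seed,
                   mode = "ternary", mg_constants = mgc))
  g_mg <- generate_isotherm(pair$mg)
  g_no <- generate_isotherm(pair$nomg)
  tf <- fit_ternary(g_mg$sample, g_no$sample,
                    pair$mg$protocol, pair$nomg$protocol, mgc)
  ternary <- purrr::map_dfr(tf$estimates$term, function(term) {
    tv <- ternary_truth[[sub("_kcal$", "_kcal", term)]]
    est <- tf$estimates$estimate[tf$estimates$term == term]
    tibble::tibble(experiment = "ternary_noise_free", parameter = term,
                   truth = tv, median_estimate = est,
                   median_rel_error = abs(est - tv) / abs(tv))
  })

  report <- dplyr::bind_rows(one_site, vant_hoff, ternary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(report, file.path(out_dir, "synthetic_recovery.csv"))
  }
  report
}
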