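# Forward model of per-injection ITC heats for a perfusion cell.
# Convention: the constant-volume overfilled cell is continuously
# perfused, so every cell total is an exact state function of the
# cumulative injected volume v (exponential dilution; the familiar
# half-volume (1 +/- v/2V0) correction factors are the Pade approximant
# of this exponential). Displaced liquid carries the instantaneous cell
# composition; its heat contribution is integrated per injection by
# 3-point Gauss-Legendre quadrature, which makes the cumulative heat
# independent of how the injection schedule is partitioned. Heats are
# reported both as raw ucal and normalized kcal per mol of injectant.

#' Titration protocol
#'
#' Describes one ITC experiment: cell and injection geometry,
#' concentrations, temperature and the total Mg(2+) present in both cell
#' and syringe (matched, as in a properly dialysed experiment).
#'
#' @param cell_volume_uL Active cell volume, uL.
#' @param injection_volumes_uL Ordered injection volumes, uL (typically
#'   15-20 injections).
#' @param syringe_mM Ligand concentration in the syringe, mM.
#' @param cell_uM Protein concentration in the cell, uM.
#' @param temperature_C Temperature, degC.
#' @param total_Mg_mM Total MgCl2 in cell and syringe, mM (0 for the
#'   EDTA/metal-free condition).
#' @param discard_first Discard the first injection when fitting (common
#'   practice: the first aliquot is diluted by diffusion at the syringe
#'   tip). The injection is kept in the concentration bookkeeping.
#' @return An object of class `titration_protocol`.
#' @export
titration_protocol <- function(cell_volume_uL = 200,
                               injection_volumes_uL = rep(2, 19),
                               syringe_mM = 2.5,
                               cell_uM = 40,
                               temperature_C = 30,
                               total_Mg_mM = 0,
                               discard_first = TRUE) {
  stopifnot(
    "cell_volume_uL must be > 0" = cell_volume_uL > 0,
    "injection volumes must all be > 0" = all(injection_volumes_uL > 0),
    "concentrations must be >= 0" = syringe_mM >= 0 && cell_uM >= 0 &&
      total_Mg_mM >= 0
  )
  structure(
    list(cell_volume_uL = cell_volume_uL,
         injection_volumes_uL = injection_volumes_uL,
         syringe_mM = syringe_mM, cell_uM = cell_uM,
         temperature_C = temperature_C, total_Mg_mM = total_Mg_mM,
         discard_first = discard_first),
    class = "titration_protocol"
  )
}

#' @export
print.titration_protocol <- function(x, ...) {
  cat(sprintf(
    "<titration_protocol> %g uL cell, %d injections (%g uL total), %g mM syringe, %g uM cell, %g degC, %g mM Mg%s\n",
    x$cell_volume_uL, length(x$injection_volumes_uL),
    sum(x$injection_volumes_uL), x$syringe_mM, x$cell_uM,
    x$temperature_C, x$total_Mg_mM,
    if (x$discard_first) ", first injection discarded in fits" else ""))
  invisible(x)
}

# Cell totals as state functions of cumulative injected volume v (L):
# protein decays as exp(-v/V0); syringe components relax towards their
# syringe concentration.
total_at <- function(v, c0, c_syr, V0) {
  f <- exp(-v / V0)
  c0 * f + c_syr * (1 - f)
}

# 5-point Gauss-Legendre nodes/weights on [-1, 1]
GL5_X <- c(-sqrt(5 + 2 * sqrt(10 / 7)) / 3, -sqrt(5 - 2 * sqrt(10 / 7)) / 3,
           0,
           sqrt(5 - 2 * sqrt(10 / 7)) / 3, sqrt(5 + 2 * sqrt(10 / 7)) / 3)
GL5_W <- c((322 - 13 * sqrt(70)) / 900, (322 + 13 * sqrt(70)) / 900,
           128 / 225,
           (322 + 13 * sqrt(70)) / 900, (322 - 13 * sqrt(70)) / 900)

#' Predict per-injection ITC heats
#'
#' Forward model: the cell totals follow the continuous-perfusion
#' displacement dilution (exact state functions of the cumulative
#' injected volume, with the half-volume displacement correction),
#' speciation is solved at the post-injection state, and the injection
#' heat is \eqn{Q_i = \sum_s \Delta H_s \, \Delta n_s}
#' where \eqn{\Delta n_s} counts the moles of complex `s` formed during
#' the injection: the change of bound material in the cell, plus the
#' bound material carried out with the displaced liquid (integrated by
#' Gauss-Legendre quadrature over the injection), net of the moles
#' delivered pre-formed from the syringe (Mg-nucleotide species).
#' Cumulative heat is therefore independent of how the injection
#' schedule is partitioned.
#'
#' @param protocol A [titration_protocol()].
#' @param params For `mode = "one_site"`: a list or one-row data frame
#'   with `n`, `Kb_mM`, `dH_kcal` (e.g. [binding_parameters()]). For
#'   `mode = "ternary"`: a list with `n`, `K_EG`, `K_EMG` (M^-1),
#'   `dH_EG_kcal`, `dH_EMG_kcal`.
#' @param mode `"one_site"` or `"ternary"`.
#' @param mg_constants An [mg_constants()] object (required for ternary).
#' @return A tibble of class `itc_isotherm` with columns `injection`,
#'   `inj_volume_uL`, `molar_ratio` (cumulative ligand:protein in the
#'   cell), `Q_ucal`, `ndh_kcal_per_mol`, and attributes `protocol` and
#'   `blank_subtracted`.
#' @export
predict_injection_heats <- function(protocol, params,
                                    mode = c("one_site", "ternary"),
                                    mg_constants = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(protocol, "titration_protocol"))
  if (mode == "ternary" && is.null(mg_constants)) {
    stop("mode = 'ternary' requires mg_constants")
  }

  V0 <- protocol$cell_volume_uL * 1e-6        # L
  dvs <- protocol$injection_volumes_uL * 1e-6 # L
  L_syr <- protocol$syringe_mM * 1e-3         # M
  Mg_tot0 <- protocol$total_Mg_mM * 1e-3      # M
  E_tot <- protocol$cell_uM * 1e-6            # M

  degenerate <- L_syr == 0
  if (degenerate) {
    warning("syringe ligand concentration is zero; all heats are zero")
  }

  p <- as.list(params)
  if (mode == "one_site") {
    stopifnot(all(c("n", "Kb_mM", "dH_kcal") %in% names(p)))
    K_M <- p$Kb_mM * 1000
    species <- "EB"
    dH <- c(EB = p$dH_kcal)
    syr_species <- c(EB = 0)
  } else {
    stopifnot(all(c("n", "K_EG", "K_EMG", "dH_EG_kcal", "dH_EMG_kcal") %in%
                    names(p)))
    species <- c("EG", "EMG", "MgG", "Mg2G")
    dH <- c(EG = p$dH_EG_kcal, EMG = p$dH_EMG_kcal,
            MgG = mg_constants$dH_MgG, Mg2G = mg_constants$dH_Mg2G)
    syr <- if (degenerate) {
      tibble::tibble(G = 0, MgG = 0, Mg2G = 0, Mg = Mg_tot0)
    } else {
      solve_mg_nucleotide(L_syr, Mg_tot0, mg_constants)
    }
    syr_species <- c(EG = 0, EMG = 0, MgG = syr$MgG, Mg2G = syr$Mg2G)
  }

  # bound-species concentrations at cumulative injected volume v
  bound_at <- function(v) {
    E_t <- p$n * total_at(v, E_tot, 0, V0)
    G_t <- total_at(v, 0, L_syr, V0)
    if (mode == "one_site") {
      c(EB = binary_complex(E_t, G_t, K_M))
    } else {
      s <- solve_ternary(E_t, G_t, Mg_tot0, p$K_EG, p$K_EMG, mg_constants)
      c(EG = s$EG, EMG = s$EMG, MgG = s$MgG, Mg2G = s$Mg2G)
    }
  }

  n_inj <- length(dvs)
  Q_ucal <- numeric(n_inj)
  ndh <- numeric(n_inj)
  ratio <- numeric(n_inj)

  v_prev <- 0
  prev <- bound_at(0)

  for (i in seq_len(n_inj)) {
    dv <- dvs[i]
    v_cur <- v_prev + dv
    cur <- bound_at(v_cur)
    # bound material expelled with the displaced liquid over this
    # injection: integral of the instantaneous bound concentrations
    mid <- (v_prev + v_cur) / 2
    half <- dv / 2
    expelled <- Reduce(`+`, lapply(seq_along(GL5_X), function(k) {
      GL5_W[k] * bound_at(mid + half * GL5_X[k])
    })) * half
    formed <- V0 * (cur - prev) + expelled - dv * syr_species[names(cur)]
    Q_kcal <- sum(dH[names(cur)] * formed)
    Q_ucal[i] <- Q_kcal * 1e9
    ndh[i] <- if (degenerate) 0 else Q_kcal / (dv * L_syr)
    E_now <- total_at(v_cur, E_tot, 0, V0)
    ratio[i] <- if (E_now > 0) {
      total_at(v_cur, 0, L_syr, V0) / E_now
    } else {
      NA_real_
    }
    v_prev <- v_cur
    prev <- cur
  }

  new_isotherm(
    tibble::tibble(
      injection = seq_len(n_inj),
      inj_volume_uL = protocol$injection_volumes_uL,
      molar_ratio = ratio,
      Q_ucal = Q_ucal,
      ndh_kcal_per_mol = ndh
    ),
    protocol = protocol, blank_subtracted = FALSE
  )
}

new_isotherm <- function(data, protocol = NULL, blank_subtracted = FALSE) {
  out <- tibble::as_tibble(data)
  class(out) <- c("itc_isotherm", class(out))
  attr(out, "protocol") <- protocol
  attr(out, "blank_subtracted") <- blank_subtracted
  out
}

#' Subtract the ligand-dilution blank
#'
#' Pointwise subtraction of a buffer-titration blank from a sample
#' isotherm measured with the same injection schedule.
#'
#' @param sample,blank `itc_isotherm` tibbles with identical injection
#'   schedules.
#' @return The blank-subtracted isotherm (attribute `blank_subtracted`
#'   set).
#' @export
subtract_dilution <- function(sample, blank) {
  if (nrow(sample) != nrow(blank) ||
      !isTRUE(all.equal(sample$inj_volume_uL, blank$inj_volume_uL))) {
    stop("sample and blank injection schedules do not match")
  }
  proto <- attr(sample, "protocol")
  out <- sample
  out$Q_ucal <- sample$Q_ucal - blank$Q_ucal
  if (!is.null(proto) && proto$syringe_mM > 0) {
    dv_L <- out$inj_volume_uL * 1e-6
    out$ndh_kcal_per_mol <- (out$Q_ucal * 1e-9) /
      (dv_L * proto$syringe_mM * 1e-3)
  } else {
    out$ndh_kcal_per_mol <- sample$ndh_kcal_per_mol - blank$ndh_kcal_per_mol
  }
  new_isotherm(out, protocol = proto, blank_subtracted = TRUE)
}

#' Read and write isotherm CSV files
#'
#' Columns: `injection`, `inj_volume_uL`, `Q_ucal`, and optionally
#' `molar_ratio` and `ndh_kcal_per_mol`. Lines starting with `#` are
#' treated as comments.
#'
#' @param path File path.
#' @return `read_isotherm_csv()` returns an `itc_isotherm` tibble.
#' @export
read_isotherm_csv <- function(path) {
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("injection", "inj_volume_uL", "Q_ucal") %in% names(d)))
  new_isotherm(d)
}

#' @rdname read_isotherm_csv
#' @param isotherm An `itc_isotherm` tibble.
#' @export
write_isotherm_csv <- function(isotherm, path) {
  readr::write_csv(tibble::as_tibble(isotherm), path)
  invisible(path)
}
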