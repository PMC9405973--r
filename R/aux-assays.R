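# Fitting machinery for auxiliary assays: Michaelis-Menten kinetics
# (PNP-coupled GTP hydrolysis) and ligand-depletion fluorescence binding
# (mant-GTP).

#' Fit a Michaelis-Menten model
#'
#' Least-squares fit of `v = Vmax S / (Km + S)`; the catalytic constant
#' is derived as `kcat = Vmax / [E]`.
#'
#' @param data A data frame with columns `substrate_uM` and
#'   `rate_uM_per_min` (>= 4 substrate levels).
#' @param enzyme_conc_uM Enzyme concentration, uM.
#' @return An object of class `mm_fit`; `$estimates` holds `Km_uM`,
#'   `Vmax_uM_per_min`, `kcat_per_min` with standard errors.
#' @export
fit_michaelis_menten <- function(data, enzyme_conc_uM) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("substrate_uM", "rate_uM_per_min") %in% names(data)))
  if (length(unique(data$substrate_uM)) < 4) {
    stop("need >= 4 substrate levels")
  }
  S <- data$substrate_uM
  v <- data$rate_uM_per_min
  Vmax0 <- max(v)
  Km0 <- S[which.min(abs(v - Vmax0 / 2))]
  if (Km0 <= 0) Km0 <- stats::median(S)

  fit <- minpack.lm::nlsLM(
    rate_uM_per_min ~ Vmax * substrate_uM / (Km + substrate_uM),
    data = data, start = list(Vmax = Vmax0, Km = Km0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  Km <- cf["Km", "Estimate"]

  if (all(S < Km / 5) || all(S > Km * 5)) {
    warning("substrate range does not span Km: parameters poorly identifiable")
  }

  Vmax <- cf["Vmax", "Estimate"]
  structure(
    list(
      estimates = tibble::tibble(
        term = c("Km_uM", "Vmax_uM_per_min", "kcat_per_min"),
        estimate = c(Km, Vmax, Vmax / enzyme_conc_uM),
        std_error = c(cf["Km", "Std. Error"], cf["Vmax", "Std. Error"],
                      cf["Vmax", "Std. Error"] / enzyme_conc_uM)
      ),
      enzyme_conc_uM = enzyme_conc_uM, fit = fit, data = data
    ),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit>\n")
  print(x$estimates)
  invisible(x)
}

#' Fraction of receptor bound with ligand depletion
#'
#' Physical root of the single-site quadratic at total ligand `L`, total
#' receptor `R` and dissociation constant `Kd` (all uM); the
#' `receptor_conc -> 0` limit is the hyperbola `L / (Kd + L)`.
#'
#' @param L_total_uM Total ligand, uM (vectorized).
#' @param receptor_uM Total receptor, uM.
#' @param Kd_uM Dissociation constant, uM.
#' @return Fraction of receptor bound.
#' @export
fraction_bound_depletion <- function(L_total_uM, receptor_uM, Kd_uM) {
  if (receptor_uM <= 0) return(L_total_uM / (Kd_uM + L_total_uM))
  b <- L_total_uM + receptor_uM + Kd_uM
  C <- 2 * L_total_uM * receptor_uM /
    (b + sqrt(pmax(b^2 - 4 * L_total_uM * receptor_uM, 0)))
  C / receptor_uM
}

#' Fit a fluorescence saturation binding curve
#'
#' Fits `F = F0 + (Fmax - F0) * fraction_bound`, with the bound fraction
#' from the single-site quadratic accounting for ligand depletion
#' (`depletion = TRUE`, the default) or the hyperbolic no-depletion
#' limit.
#'
#' @param data A data frame with columns `ligand_uM` and `fluorescence`
#'   (>= 5 ligand levels).
#' @param receptor_uM Total receptor concentration, uM.
#' @param depletion Account for ligand depletion by the receptor.
#' @return An object of class `fluor_fit`; `$estimates` holds `Kd_uM`,
#'   `F0`, `Fmax` with standard errors.
#' @export
fit_fluorescence_kd <- function(data, receptor_uM, depletion = TRUE) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("ligand_uM", "fluorescence") %in% names(data)))
  if (length(unique(data$ligand_uM)) < 5) {
    stop("need >= 5 ligand levels")
  }
  F0_0 <- data$fluorescence[which.min(data$ligand_uM)]
  Fmax0 <- data$fluorescence[which.max(data$ligand_uM)]
  if (Fmax0 == F0_0) Fmax0 <- F0_0 + 1
  half <- F0_0 + (Fmax0 - F0_0) / 2
  Kd0 <- data$ligand_uM[which.min(abs(data$fluorescence - half))]
  if (Kd0 <= 0) Kd0 <- stats::median(data$ligand_uM)

  R_eff <- if (depletion) receptor_uM else 0
  fit <- minpack.lm::nlsLM(
    fluorescence ~ F0 + (Fmax - F0) *
      fraction_bound_depletion(ligand_uM, R_eff, Kd),
    data = data, start = list(F0 = F0_0, Fmax = Fmax0, Kd = Kd0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients

  max_frac <- max(fraction_bound_depletion(
    data$ligand_uM, R_eff, cf["Kd", "Estimate"]))
  if (max_frac < 0.5) {
    warning(sprintf(
      "saturation never reached (max bound fraction %.2f): Kd poorly identifiable",
      max_frac))
  }

  structure(
    list(
      estimates = tibble::tibble(
        term = c("Kd_uM", "F0", "Fmax"),
        estimate = cf[c("Kd", "F0", "Fmax"), "Estimate"],
        std_error = cf[c("Kd", "F0", "Fmax"), "Std. Error"]
      ),
      receptor_uM = receptor_uM, depletion = depletion,
      fit = fit, data = data
    ),
    class = "fluor_fit"
  )
}

#' @export
print.fluor_fit <- function(x, ...) {
  cat(sprintf("<fluor_fit>%s\n",
              if (x$depletion) " (ligand depletion)" else " (hyperbolic)"))
  print(x$estimates)
  invisible(x)
}
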