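# Nonlinear least-squares fitting of ITC isotherms against the forward
# model, via Levenberg-Marquardt (minpack.lm::nls.lm) on log-transformed
# positive parameters. Multi-start over a c-value heuristic makes the
# result deterministic and robust to local minima.

fit_observed <- function(isotherm, protocol) {
  keep <- rep(TRUE, nrow(isotherm))
  if (isTRUE(protocol$discard_first)) keep[1] <- FALSE
  list(y = isotherm$ndh_kcal_per_mol[keep], keep = keep)
}

onesite_predict <- function(theta, protocol, fix_n = NULL) {
  # theta = c(log_n, log_K_mM, dH) or c(log_K_mM, dH) when n is fixed
  if (is.null(fix_n)) {
    params <- list(n = exp(theta[1]), Kb_mM = exp(theta[2]),
                   dH_kcal = theta[3])
  } else {
    params <- list(n = fix_n, Kb_mM = exp(theta[1]), dH_kcal = theta[2])
  }
  predict_injection_heats(protocol, params, mode = "one_site")$ndh_kcal_per_mol
}

#' Fit a one-site binding model to an isotherm
#'
#' Least-squares minimization of predicted vs observed normalized heats
#' over (`n`, `Kb_mM`, `dH_kcal`), with asymptotic standard errors from
#' the Jacobian at the optimum. Three deterministic starts are used (a
#' c-value heuristic for K, and the same halved and doubled); the best
#' final fit is returned. An identifiability warning is attached when the
#' Wiseman c-value `n K [cell]` falls outside [0.1, 1e5].
#'
#' @param isotherm An `itc_isotherm` tibble (blank-subtracted).
#' @param protocol The [titration_protocol()] of the experiment.
#' @param init Optional [binding_parameters()]-like list with starting
#'   `n`, `Kb_mM`, `dH_kcal`.
#' @param fix_n Optional fixed stoichiometry; when supplied only
#'   (`Kb_mM`, `dH_kcal`) are floated.
#' @return An object of class `itc_onesite_fit` with tidy()/glance()
#'   methods; `$estimates` is a tibble of term, estimate, std_error.
#' @export
fit_one_site <- function(isotherm, protocol, init = NULL, fix_n = NULL) {
  obs <- fit_observed(isotherm, protocol)
  if (length(obs$y) < 5) stop("need >= 5 informative injections")

  E0 <- protocol$cell_uM * 1e-6
  if (is.null(init)) {
    dH0 <- obs$y[which.max(abs(obs$y))]
    if (dH0 == 0) dH0 <- 1
    K0_mM <- 5 / (E0 * 1e6) # c-value heuristic: c = n K [cell] ~ 5
    init <- list(n = 1, Kb_mM = K0_mM, dH_kcal = dH0)
  } else {
    init <- as.list(init)
  }

  resid_fn <- function(theta) {
    onesite_predict(theta, protocol, fix_n)[obs$keep] - obs$y
  }

  starts <- lapply(c(1, 0.5, 2), function(f) {
    if (is.null(fix_n)) {
      c(log(init$n), log(init$Kb_mM * f), init$dH_kcal)
    } else {
      c(log(init$Kb_mM * f), init$dH_kcal)
    }
  })

  fits <- lapply(starts, function(s) {
    tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("one-site fit failed from every start")
  best <- fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]

  theta <- best$par
  m <- length(obs$y)
  np <- length(theta)
  sigma2 <- stats::deviance(best) / max(m - np, 1)
  covm <- tryCatch(sigma2 * solve(best$hessian),
                   error = function(e) matrix(NA_real_, np, np))
  se_theta <- sqrt(pmax(diag(covm), 0))

  if (is.null(fix_n)) {
    n_hat <- exp(theta[1]); K_hat <- exp(theta[2]); dH_hat <- theta[3]
    se <- c(n = n_hat * se_theta[1], Kb_mM = K_hat * se_theta[2],
            dH_kcal = se_theta[3])
  } else {
    n_hat <- fix_n; K_hat <- exp(theta[1]); dH_hat <- theta[2]
    se <- c(n = 0, Kb_mM = K_hat * se_theta[1], dH_kcal = se_theta[2])
  }

  c_value <- n_hat * (K_hat * 1000) * E0
  ident_warn <- c_value < 0.1 || c_value > 1e5
  if (ident_warn) {
    warning(sprintf(
      "c-value %.3g outside [0.1, 1e5]: K poorly identifiable", c_value))
  }

  fitted_all <- onesite_predict(theta, protocol, fix_n)
  structure(
    list(
      estimates = tibble::tibble(
        term = c("n", "Kb_mM", "dH_kcal"),
        estimate = c(n_hat, K_hat, dH_hat),
        std_error = unname(se)
      ),
      c_value = c_value, identifiability_warning = ident_warn,
      deviance = stats::deviance(best), sigma = sqrt(sigma2),
      n_obs = m, convergence = best$info,
      fitted = fitted_all, keep = obs$keep,
      isotherm = isotherm, protocol = protocol
    ),
    class = "itc_onesite_fit"
  )
}

#' @export
print.itc_onesite_fit <- function(x, ...) {
  cat("<itc_onesite_fit>\n")
  print(x$estimates)
  cat(sprintf("  c-value %.3g, residual sd %.3g kcal/mol (%d injections)\n",
              x$c_value, x$sigma, x$n_obs))
  invisible(x)
}

ternary_predict <- function(theta, protocols, n, mg_constants) {
  params <- list(n = n, K_EG = exp(theta[1]), K_EMG = exp(theta[2]),
                 dH_EG_kcal = theta[3], dH_EMG_kcal = theta[4])
  lapply(protocols, function(pr) {
    predict_injection_heats(pr, params, mode = "ternary",
                            mg_constants = mg_constants)$ndh_kcal_per_mol
  })
}

#' Jointly fit the ternary model to a paired +/-Mg experiment
#'
#' Joint least squares over two isotherms measured at the same
#' temperature, one with Mg(2+) and one metal-free. The metal-free
#' isotherm pins `K_EG`/`dH_EG`; the +Mg isotherm then determines
#' `K_EMG`/`dH_EMG` through the coupled-equilibria speciation.
#'
#' @param isotherm_mg,isotherm_nomg Blank-subtracted `itc_isotherm`s.
#' @param protocol_mg,protocol_nomg Their [titration_protocol()]s; they
#'   must share the temperature and differ in total Mg.
#' @param mg_constants An [mg_constants()] object.
#' @param n Stoichiometry (fixed during the fit).
#' @param init Optional list with starting `K_EG`, `K_EMG` (M^-1),
#'   `dH_EG_kcal`, `dH_EMG_kcal`.
#' @return An object of class `itc_ternary_fit`; `$estimates` holds the
#'   four parameters with standard errors, `$kappa` the heterotropic
#'   ratio `K_EMG / K_EG`.
#' @export
fit_ternary <- function(isotherm_mg, isotherm_nomg,
                        protocol_mg, protocol_nomg,
                        mg_constants, n = 1, init = NULL) {
  if (protocol_mg$temperature_C != protocol_nomg$temperature_C) {
    stop("paired experiments must share the temperature")
  }
  if (protocol_mg$total_Mg_mM == protocol_nomg$total_Mg_mM &&
      protocol_mg$total_Mg_mM == 0) {
    # Both metal-free: K_EMG never enters the model; fall back to the
    # one-site fit of the pooled metal-free data for K_EG.
    message("both experiments are metal-free; returning one-site K_EG fit")
    f <- fit_one_site(isotherm_nomg, protocol_nomg, fix_n = n)
    est <- f$estimates
    return(structure(
      list(
        estimates = tibble::tibble(
          term = c("K_EG", "K_EMG", "dH_EG_kcal", "dH_EMG_kcal"),
          estimate = c(est$estimate[est$term == "Kb_mM"] * 1000, NA,
                       est$estimate[est$term == "dH_kcal"], NA),
          std_error = c(est$std_error[est$term == "Kb_mM"] * 1000, NA,
                        est$std_error[est$term == "dH_kcal"], NA)
        ),
        kappa = NA_real_, kappa_se = NA_real_, degenerate = TRUE,
        onesite_fit = f
      ),
      class = "itc_ternary_fit"
    ))
  }
  if (protocol_mg$total_Mg_mM == protocol_nomg$total_Mg_mM) {
    stop("experiments have identical Mg conditions: ternary parameters are rank-deficient")
  }

  obs_mg <- fit_observed(isotherm_mg, protocol_mg)
  obs_no <- fit_observed(isotherm_nomg, protocol_nomg)
  protocols <- list(mg = protocol_mg, nomg = protocol_nomg)

  if (is.null(init)) {
    f_no <- fit_one_site(isotherm_nomg, protocol_nomg, fix_n = n)
    K_EG0 <- f_no$estimates$estimate[f_no$estimates$term == "Kb_mM"] * 1000
    dH_EG0 <- f_no$estimates$estimate[f_no$estimates$term == "dH_kcal"]
    f_mg <- fit_one_site(isotherm_mg, protocol_mg, fix_n = n)
    K_app <- f_mg$estimates$estimate[f_mg$estimates$term == "Kb_mM"] * 1000
    dH_EMG0 <- f_mg$estimates$estimate[f_mg$estimates$term == "dH_kcal"]
    # invert the apparent-constant relation at [Mg] ~ total Mg
    Mg <- protocol_mg$total_Mg_mM * 1e-3
    K1 <- mg_constants$K_MgG; K2 <- mg_constants$K_Mg2G
    K_EMG0 <- (K_app * (1 + K1 * Mg + K1 * K2 * Mg^2) - K_EG0) / (K1 * Mg)
    if (!is.finite(K_EMG0) || K_EMG0 <= 0) K_EMG0 <- K_app
    init <- list(K_EG = K_EG0, K_EMG = K_EMG0,
                 dH_EG_kcal = dH_EG0, dH_EMG_kcal = dH_EMG0)
  }

  resid_fn <- function(theta) {
    pred <- ternary_predict(theta, protocols, n, mg_constants)
    c(pred$mg[obs_mg$keep] - obs_mg$y, pred$nomg[obs_no$keep] - obs_no$y)
  }

  theta0 <- c(log(init$K_EG), log(init$K_EMG),
              init$dH_EG_kcal, init$dH_EMG_kcal)
  best <- minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 500, ftol = 1e-15, ptol = 1e-15))

  theta <- best$par
  m <- length(obs_mg$y) + length(obs_no$y)
  sigma2 <- stats::deviance(best) / max(m - 4, 1)
  covm <- tryCatch(sigma2 * solve(best$hessian),
                   error = function(e) matrix(NA_real_, 4, 4))
  se_theta <- sqrt(pmax(diag(covm), 0))
  K_EG <- exp(theta[1]); K_EMG <- exp(theta[2])
  kappa <- K_EMG / K_EG
  # delta method on log K difference
  kappa_se <- kappa * sqrt(max(
    se_theta[1]^2 + se_theta[2]^2 - 2 * covm[1, 2], 0))

  structure(
    list(
      estimates = tibble::tibble(
        term = c("K_EG", "K_EMG", "dH_EG_kcal", "dH_EMG_kcal"),
        estimate = c(K_EG, K_EMG, theta[3], theta[4]),
        std_error = c(K_EG * se_theta[1], K_EMG * se_theta[2],
                      se_theta[3], se_theta[4])
      ),
      kappa = kappa, kappa_se = kappa_se, degenerate = FALSE,
      deviance = stats::deviance(best), sigma = sqrt(sigma2),
      n_obs = m, convergence = best$info
    ),
    class = "itc_ternary_fit"
  )
}

#' @export
print.itc_ternary_fit <- function(x, ...) {
  cat("<itc_ternary_fit>\n")
  print(x$estimates)
  cat(sprintf("  kappa = K_EMG/K_EG = %.3g\n", x$kappa))
  invisible(x)
}
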