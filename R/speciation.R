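# Equilibrium speciation of protein (E) / nucleotide (G) / Mg(2+)
# mixtures. Species: E, G, Mg, MgG, Mg2G, EG, EMG. The protein binds the
# free nucleotide (K_EG) or the mono-magnesium form (K_EMG); the
# di-magnesium form Mg2G (triphosphates only) is not recognised.
# Concentrations in M, association constants in M^-1 throughout this file.

#' Single-site binding speciation (closed form)
#'
#' Physical root of the one-site quadratic
#' \eqn{K (P_t - C)(L_t - C) = C}.
#'
#' @param total_protein,total_ligand Total concentrations, M (vectorized).
#' @param K Association constant, M^-1.
#' @return A tibble with columns `free_protein`, `free_ligand`, `complex`
#'   (M); mass balances hold to machine precision.
#' @export
solve_binary_speciation <- function(total_protein, total_ligand, K) {
  if (any(total_protein < 0) || any(total_ligand < 0) || any(K < 0)) {
    stop("totals and K must be non-negative")
  }
  n <- max(length(total_protein), length(total_ligand), length(K))
  P <- rep_len(total_protein, n)
  L <- rep_len(total_ligand, n)
  K <- rep_len(K, n)
  C <- ifelse(K == 0, 0, {
    b <- P + L + 1 / K
    # numerically stable smaller quadratic root: 2PL / (b + sqrt(b^2-4PL))
    2 * P * L / (b + sqrt(pmax(b^2 - 4 * P * L, 0)))
  })
  C <- pmin(C, P, L) # guard rounding at the stoichiometric limit
  tibble::tibble(free_protein = P - C, free_ligand = L - C, complex = C)
}

#' Mg(2+)-nucleotide speciation
#'
#' Stepwise equilibria `[MgG] = K_MgG [Mg][G]`,
#' `[Mg2G] = K_Mg2G [Mg][MgG]` solved by one-dimensional root finding on
#' the free-Mg mass balance (the nucleotide balance is eliminated in
#' closed form).
#'
#' @param total_G,total_Mg Total nucleotide and magnesium, M.
#' @param constants An [mg_constants()] object.
#' @return A tibble with columns `G`, `MgG`, `Mg2G`, `Mg` (free
#'   concentrations, M).
#' @export
solve_mg_nucleotide <- function(total_G, total_Mg,
                                constants = mg_constants_for("GTP")) {
  if (total_G < 0 || total_Mg < 0) stop("totals must be non-negative")
  K1 <- constants$K_MgG
  K2 <- constants$K_Mg2G
  g_of_m <- function(m) total_G / (1 + K1 * m + K1 * K2 * m^2)
  if (total_Mg == 0 || K1 == 0) {
    m <- total_Mg
    g <- g_of_m(m)
  } else {
    resid <- function(m) {
      g <- g_of_m(m)
      m + K1 * m * g + 2 * K1 * K2 * m^2 * g - total_Mg
    }
    m <- stats::uniroot(resid, c(0, total_Mg),
                        tol = .Machine$double.eps * max(total_Mg, 1))$root
    g <- g_of_m(m)
  }
  tibble::tibble(
    G = g, MgG = K1 * m * g, Mg2G = K1 * K2 * m^2 * g, Mg = m
  )
}

# Scalar fast path of the one-site quadratic (no tibble construction);
# used in the inner loop of the forward model.
binary_complex <- function(P, L, K) {
  if (K == 0 || P == 0 || L == 0) return(0)
  b <- P + L + 1 / K
  min(2 * P * L / (b + sqrt(max(b^2 - 4 * P * L, 0))), P, L)
}

# Species concentrations implied by the three free concentrations.
ternary_species <- function(e, g, m, K_EG, K_EMG, K1, K2) {
  tibble::tibble(
    E = e, G = g, Mg = m,
    MgG = K1 * m * g,
    Mg2G = K1 * K2 * m^2 * g,
    EG = K_EG * e * g,
    EMG = K_EMG * K1 * e * m * g
  )
}

ternary_residuals <- function(e, g, m, totals, K_EG, K_EMG, K1, K2) {
  lhs_E <- e * (1 + K_EG * g + K_EMG * K1 * m * g)
  lhs_G <- g * (1 + K1 * m + K1 * K2 * m^2 + K_EG * e + K_EMG * K1 * e * m)
  lhs_Mg <- m * (1 + K1 * g + 2 * K1 * K2 * m * g + K_EMG * K1 * e * g)
  log(c(lhs_E, lhs_G, lhs_Mg) / totals)
}

#' Ternary coupled-equilibria speciation
#'
#' Simultaneous solution of the three mass balances for the species set
#' \{E, G, Mg, MgG, Mg2G, EG, EMG\} by damped Newton iteration on the
#' logarithms of the three free concentrations (which guarantees
#' positivity), initialized from the uncoupled analytic solution.
#' Degenerate totals (any total zero) reduce exactly to the corresponding
#' lower-dimensional problem.
#'
#' @param total_E,total_G,total_Mg Total concentrations, M.
#' @param K_EG,K_EMG Association constants of the protein for the free and
#'   mono-Mg nucleotide, M^-1.
#' @param constants An [mg_constants()] object.
#' @param tol Absolute tolerance on the log mass-balance residuals.
#' @param max_iter Iteration cap; exceeding it is an error naming the
#'   worst residual.
#' @return A one-row tibble with columns `E`, `G`, `Mg`, `MgG`, `Mg2G`,
#'   `EG`, `EMG` (free/complex concentrations, M).
#' @examples
#' solve_ternary(40e-6, 500e-6, 5e-3, K_EG = 1.56e5, K_EMG = 6.4e4,
#'               constants = mg_constants(K_MgG = 1e4))
#' @export
solve_ternary <- function(total_E, total_G, total_Mg, K_EG, K_EMG,
                          constants = mg_constants_for("GTP"),
                          tol = 1e-12, max_iter = 200) {
  if (total_E < 0 || total_G < 0 || total_Mg < 0) {
    stop("totals must be non-negative")
  }
  if (K_EG < 0 || K_EMG < 0) stop("association constants must be >= 0")
  K1 <- constants$K_MgG
  K2 <- constants$K_Mg2G

  # Degenerate reductions keep the solver strictly positive-dimensional.
  if (total_G == 0) {
    return(ternary_species(total_E, 0, total_Mg, K_EG, K_EMG, K1, K2))
  }
  if (total_E == 0) {
    s <- solve_mg_nucleotide(total_G, total_Mg, constants)
    return(ternary_species(0, s$G, s$Mg, K_EG, K_EMG, K1, K2))
  }
  if (total_Mg == 0 || K1 == 0) {
    b <- solve_binary_speciation(total_E, total_G, K_EG)
    return(ternary_species(b$free_protein, b$free_ligand, total_Mg,
                           K_EG, K_EMG, K1, K2))
  }

  totals <- c(total_E, total_G, total_Mg)

  # Initial guess: Mg-nucleotide speciation without protein, then the
  # protein equilibrated against the Mg-averaged apparent constant.
  s0 <- solve_mg_nucleotide(total_G, total_Mg, constants)
  K_app <- apparent_constant(K_EG, K_EMG, s0$Mg, constants)
  b0 <- solve_binary_speciation(total_E, total_G, K_app)
  x <- log(pmax(c(b0$free_protein, s0$G * b0$free_ligand / total_G, s0$Mg),
                1e-300))

  fx <- ternary_residuals(exp(x)[1], exp(x)[2], exp(x)[3],
                          totals, K_EG, K_EMG, K1, K2)
  for (iter in seq_len(max_iter)) {
    if (max(abs(fx)) < tol) break
    # numerical Jacobian of the log-residuals in log-concentrations
    J <- matrix(0, 3, 3)
    h <- 1e-7
    for (j in 1:3) {
      xp <- x
      xp[j] <- xp[j] + h
      fp <- ternary_residuals(exp(xp)[1], exp(xp)[2], exp(xp)[3],
                              totals, K_EG, K_EMG, K1, K2)
      J[, j] <- (fp - fx) / h
    }
    step <- tryCatch(solve(J, fx), error = function(e) fx) # fall back to
    # a gradient-like step if J is singular at the current iterate
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      fn <- ternary_residuals(exp(xn)[1], exp(xn)[2], exp(xn)[3],
                              totals, K_EG, K_EMG, K1, K2)
      if (all(is.finite(fn)) && max(abs(fn)) < max(abs(fx))) break
      lambda <- lambda / 2
      if (lambda < 1e-12) break
    }
    x <- xn
    fx <- fn
    if (iter == max_iter && max(abs(fx)) >= tol) {
      stop(sprintf(
        "ternary speciation did not converge in %d iterations (worst log-residual %.3g)",
        max_iter, max(abs(fx))))
    }
  }
  ternary_species(exp(x)[1], exp(x)[2], exp(x)[3], K_EG, K_EMG, K1, K2)
}

#' Mg-averaged apparent association constant
#'
#' The association constant of the protein for total uncomplexed
#' nucleotide at a given free Mg(2+) concentration:
#' \deqn{K_{app} = \frac{K_{EG} + K_{EMG} K_{MgG} [Mg]}{1 + K_{MgG}[Mg] +
#'   K_{MgG} K_{Mg2G} [Mg]^2}}
#'
#' @param K_EG,K_EMG Intrinsic association constants, M^-1.
#' @param free_Mg Free Mg(2+) concentration, M (vectorized).
#' @param constants An [mg_constants()] object.
#' @return Apparent association constant, M^-1.
#' @export
apparent_constant <- function(K_EG, K_EMG, free_Mg,
                              constants = mg_constants_for("GTP")) {
  if (any(free_Mg < 0)) stop("free_Mg must be >= 0")
  K1 <- constants$K_MgG
  K2 <- constants$K_Mg2G
  (K_EG + K_EMG * K1 * free_Mg) /
    (1 + K1 * free_Mg + K1 * K2 * free_Mg^2)
}
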