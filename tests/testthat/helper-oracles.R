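# Independent oracles used across the suite. These deliberately avoid
# the package's solver code paths: root finding is plain bisection on
# mass-balance residuals, and the ternary oracle nests bisections with a
# closed-form innermost elimination.

# 1-D bisection solver for f on [lo, hi] with f(lo) <= 0 <= f(hi)
bisect <- function(f, lo, hi, iters = 200) {
  flo <- f(lo)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# one-site complex concentration via bisection on the mass balance
oracle_binary_complex <- function(P, L, K) {
  if (K == 0 || P == 0 || L == 0) return(0)
  f <- function(C) K * (P - C) * (L - C) - C
  bisect(f, min(P, L), 0) # f(minPL) <= 0 <= f(0)
}

# Mg-nucleotide speciation by bisection on free Mg with closed-form G
oracle_mg_nucleotide <- function(G_tot, Mg_tot, K1, K2) {
  g_of_m <- function(m) G_tot / (1 + K1 * m + K1 * K2 * m^2)
  if (Mg_tot == 0 || K1 == 0) {
    m <- Mg_tot
  } else {
    f <- function(m) {
      g <- g_of_m(m)
      m + K1 * m * g + 2 * K1 * K2 * m^2 * g - Mg_tot
    }
    m <- bisect(f, 0, Mg_tot)
  }
  g <- g_of_m(m)
  list(G = g, MgG = K1 * m * g, Mg2G = K1 * K2 * m^2 * g, Mg = m)
}

# Ternary speciation: outer bisection on free Mg, inner bisection on
# free G, closed-form free protein.
oracle_ternary <- function(E_tot, G_tot, Mg_tot, K_EG, K_EMG, K1, K2) {
  e_of <- function(g, m) E_tot / (1 + K_EG * g + K_EMG * K1 * m * g)
  g_resid <- function(g, m) {
    e <- e_of(g, m)
    g * (1 + K1 * m + K1 * K2 * m^2 + K_EG * e + K_EMG * K1 * e * m) -
      G_tot
  }
  g_of <- function(m) {
    if (G_tot == 0) return(0)
    bisect(function(g) g_resid(g, m), 0, G_tot)
  }
  if (Mg_tot == 0 || K1 == 0) {
    m <- Mg_tot
  } else {
    mg_resid <- function(m) {
      g <- g_of(m)
      e <- e_of(g, m)
      m * (1 + K1 * g + 2 * K1 * K2 * m * g + K_EMG * K1 * e * g) - Mg_tot
    }
    m <- bisect(mg_resid, 0, Mg_tot)
  }
  g <- g_of(m)
  e <- e_of(g, m)
  list(E = e, G = g, Mg = m,
       MgG = K1 * m * g, Mg2G = K1 * K2 * m^2 * g,
       EG = K_EG * e * g, EMG = K_EMG * K1 * e * m * g)
}

# independent recursion for per-injection one-site heats: same physical
# model (continuous-perfusion totals, expelled-material integral), but
# bound concentrations from the bisection oracle and the expelled
# integral from dense-grid trapezoid integration.
oracle_onesite_heats <- function(protocol, n, Kb_mM, dH_kcal,
                                 grid_points = 2001) {
  V0 <- protocol$cell_volume_uL * 1e-6
  dvs <- protocol$injection_volumes_uL * 1e-6
  L_syr <- protocol$syringe_mM * 1e-3
  E0 <- protocol$cell_uM * 1e-6
  K <- Kb_mM * 1000
  b_at <- function(v) {
    oracle_binary_complex(n * E0 * exp(-v / V0),
                          L_syr * (1 - exp(-v / V0)), K)
  }
  v_prev <- 0
  b_prev <- b_at(0)
  out <- numeric(length(dvs))
  for (i in seq_along(dvs)) {
    v_cur <- v_prev + dvs[i]
    b_cur <- b_at(v_cur)
    vs <- seq(v_prev, v_cur, length.out = grid_points)
    bs <- vapply(vs, b_at, numeric(1))
    expelled <- sum((bs[-1] + bs[-grid_points]) / 2) * diff(vs)[1]
    out[i] <- dH_kcal * (V0 * (b_cur - b_prev) + expelled) /
      (dvs[i] * L_syr)
    v_prev <- v_cur
    b_prev <- b_cur
  }
  out
}

# closed-form Wiseman differential isotherm: d[complex]/d[ligand_total]
# at fixed protein total (the infinitesimal-injection, no-dilution limit)
wiseman_ndh <- function(Xr, c_value, dH) {
  r <- 1 / c_value
  dH * (0.5 + (1 - Xr - r) / (2 * sqrt((1 + Xr + r)^2 - 4 * Xr)))
}

expect_rel_equal <- function(actual, expected, tol, floor = 0) {
  denom <- pmax(abs(expected), floor)
  expect_true(all(abs(actual - expected) <= tol * pmax(denom, 1e-300)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) /
                                    pmax(denom, 1e-300)), tol))
}
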