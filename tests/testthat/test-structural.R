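# Structural-energetic deconvolution: scalar operations, exact closure,
# inverse composition, and the full published-table reproduction.

test_that("rigid-body heat capacity is the weighted surface sum", {
  expect_equal(cp_rigid_body(0, 0), 0)
  expect_equal(cp_rigid_body(1000, 1000), 190)
  expect_equal(cp_rigid_body(-100, 100), -71)
})

test_that("conformational split reproduces tabulated cells and closes exactly", {
  expect_equal(cp_conformational(-270, -48), -222)
  expect_equal(cp_conformational(10, -25), 35)
  expect_equal(cp_conformational(-3, -3), 0)
  # exact closure, bit for bit
  dCp_b <- c(-270, 10, -550, 30)
  dCp_rb <- c(-48, -25, -30, -11)
  conf <- cp_conformational(dCp_b, dCp_rb)
  expect_identical(dCp_rb + conf, dCp_b)
})

test_that("surface-area conversion uses the hydrophobicity-weighted
           coefficient and inverts exactly", {
  expect_equal(cp_conf_coefficient(), 0.2228, tolerance = 1e-12)
  expect_equal(asa_from_cp_conf(-222), -996.4, tolerance = 1e-3)
  expect_equal(asa_from_cp_conf(0), 0)
  expect_equal(asa_from_cp_conf(-520), -2334.0, tolerance = 1e-3)
  x <- c(-520, -222, 35, 41)
  expect_rel_equal(asa_from_cp_conf(x) * cp_conf_coefficient(), x, 1e-12)
  bad <- energetic_constants(alpha = 0.1, beta = -0.9, f_ap = 0.5)
  expect_error(asa_from_cp_conf(-222, bad), "positive")
})

test_that("the literal unweighted-polar coefficient does not reproduce the
           published surface areas", {
  # the corrected coefficient alpha f_ap + beta (1 - f_ap) = 0.2228
  # recovers the tabulated areas; the uncorrected (alpha - beta) f_ap =
  # 0.1292 form does not
  expect_equal(round_half_away(abs(-222 / 0.2228)), 996)
  expect_equal(round_half_away(abs(-520 / 0.2228)), 2334)
  literal <- (0.45 - 0.26) * 0.68
  expect_equal(literal, 0.1292, tolerance = 1e-12)
  expect_gt(abs(abs(-222 / literal) - 996), 700)
  expect_gt(abs(abs(-520 / literal) - 2334), 1600)
})

test_that("residue and rotor counts round half away from zero on magnitudes", {
  expect_equal(n_residues_from_asa(996), 21)
  expect_equal(n_residues_from_asa(-996), 21)
  expect_equal(n_residues_from_asa(0), 0)
  expect_equal(n_residues_from_asa(2334), 50)
  expect_equal(n_rotatable_bonds(-49.4), 29)
  expect_equal(n_rotatable_bonds(0), 0)
  # exact multiples of the per-rotor entropy give exact counts
  ec <- energetic_constants()
  for (k in c(1, 7, 30)) {
    expect_equal(n_rotatable_bonds(-ec$dS_per_rotor * k), k)
  }
})

test_that("entropy decomposition matches tabulated values and closes exactly", {
  d <- tibble::tibble(minus_TdS_kcal = -2.20, dCp_cal = -270,
                      temperature_C = 30) |>
    decompose_entropy()
  expect_equal(d$dS_solv_cal, 64.65, tolerance = 1e-2)
  expect_equal(d$dS_conf_cal, -49.39, tolerance = 1e-2)

  d2 <- tibble::tibble(minus_TdS_kcal = -1.0, dCp_cal = -550,
                       temperature_C = 30) |>
    decompose_entropy()
  expect_equal(d2$dS_solv_cal, 131.7, tolerance = 0.1)
  expect_equal(d2$dS_conf_cal, -120.4, tolerance = 0.1)

  # when dCp = 0 and dS_b equals the roto-translational term, dS_conf = 0
  ec <- energetic_constants()
  mTdS <- -ec$dS_rt * 303.15 / 1000
  d3 <- tibble::tibble(minus_TdS_kcal = mTdS, dCp_cal = 0,
                       temperature_C = 30) |>
    decompose_entropy()
  expect_equal(d3$dS_conf_cal, 0, tolerance = 1e-12)

  # exact closure
  set.seed(7)
  rand <- tibble::tibble(minus_TdS_kcal = stats::rnorm(20),
                         dCp_cal = stats::rnorm(20, sd = 300),
                         temperature_C = 30) |>
    decompose_entropy()
  expect_equal(rand$dS_solv_cal + rand$dS_rt_cal + rand$dS_conf_cal,
               rand$dS_cal, tolerance = 1e-12)
})

test_that("full deconvolution table reproduces every published cell for the
           mutant series", {
  fx <- load_efl1_fixtures()
  tab <- structural_energetics_table(fx$params, fx$dcp_rb, fx$constants)
  ref <- fx$reference$structural
  joined <- dplyr::inner_join(tab, ref, by = "complex_label",
                              suffix = c("", "_ref"))
  expect_equal(nrow(joined), 9)
  # counts match to +/-1 after rounding
  expect_true(all(abs(round_half_away(joined$n_conf_residues) -
                        joined$n_conf_residues_ref) <= 1))
  expect_true(all(abs(round_half_away(joined$n_rot_bonds) -
                        joined$n_rot_bonds_ref) <= 1))
  # continuous cells agree within one unit of the last printed digit for
  # every complex whose fitted dCp matches the printed value exactly
  exact <- joined[!joined$complex_label %in%
                    c("R1086Q.GTP.Mg", "R1086Q-Sdo1.GDP.Mg"), ]
  for (q in c("dCp_conf_cal", "dS_cal", "dS_solv_cal", "dS_conf_cal")) {
    expect_true(all(abs(exact[[q]] - exact[[paste0(q, "_ref")]]) <= 1),
                label = q)
  }
  expect_true(all(abs(exact$minus_dASA_conf -
                        exact$minus_dASA_conf_ref) <= 1))
})
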