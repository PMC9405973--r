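# Heterotropic cooperativity cycles and thermodynamic-cycle closure.

test_that("cycle parameters reproduce the tabulated couplings", {
  num <- binding_parameters("E.MgGTP", 30, Kb_mM = 64, dH_kcal = 1.07)
  den <- binding_parameters("E.GTP", 30, Kb_mM = 156, dH_kcal = 1.7)
  cyc <- heterotropic_cycle(num, den)
  expect_equal(cyc$kappa, 64 / 156)
  expect_equal(round_half_away(cyc$kappa, 1), 0.4)
  expect_equal(cyc$dh_kcal, -0.63, tolerance = 1e-9)

  num2 <- binding_parameters("ES.MgGDP", 30, Kb_mM = 125, dH_kcal = -3.8)
  den2 <- binding_parameters("E.MgGDP", 30, Kb_mM = 35, dH_kcal = -4.1)
  cyc2 <- heterotropic_cycle(num2, den2)
  expect_equal(round_half_away(cyc2$kappa, 1), 3.6)
  expect_equal(round_half_away(cyc2$dg_kcal, 1), -0.8)
  expect_equal(cyc2$dh_kcal, 0.3, tolerance = 1e-9)
  expect_equal(round_half_away(cyc2$minus_Tds_kcal, 1), -1.1)
})

test_that("cycle identities hold exactly and null cooperativity vanishes", {
  a <- binding_parameters("X", 30, Kb_mM = 42, dH_kcal = -3.3)
  same <- heterotropic_cycle(a, a)
  expect_equal(same$kappa, 1)
  expect_equal(same$dg_kcal, 0)
  expect_equal(same$dh_kcal, 0)
  expect_equal(same$minus_Tds_kcal, 0)

  b <- binding_parameters("Y", 30, Kb_mM = 17, dH_kcal = 2.4)
  cyc <- heterotropic_cycle(a, b)
  ec <- energetic_constants()
  expect_equal(cyc$dg_kcal,
               -ec$gas_constant / 1000 * 303.15 * log(cyc$kappa),
               tolerance = 1e-12)
  expect_equal(cyc$minus_Tds_kcal, cyc$dg_kcal - cyc$dh_kcal)

  # antisymmetry on swapping numerator and denominator
  rev <- heterotropic_cycle(b, a)
  expect_equal(rev$kappa, 1 / cyc$kappa)
  expect_equal(rev$dg_kcal, -cyc$dg_kcal)
  expect_equal(rev$dh_kcal, -cyc$dh_kcal)
  expect_equal(rev$minus_Tds_kcal, -cyc$minus_Tds_kcal)

  mismatch <- binding_parameters("Z", 25, Kb_mM = 17, dH_kcal = 2.4)
  expect_error(heterotropic_cycle(a, mismatch), "temperature")
})

test_that("kappa from the ternary fit equals the apparent-constant ratio
           in the Mg limits", {
  mgc <- mg_constants(K_MgG = 1e4, K_Mg2G = 0)
  K_EG <- 1.56e5
  K_EMG <- 6.4e4
  # at saturating Mg the apparent constant tends to K_EMG, so the
  # kappa recovered by the joint fit equals K_app(inf)/K_app(0)
  truth <- list(n = 1, K_EG = K_EG, K_EMG = K_EMG,
                dH_EG_kcal = 1.7, dH_EMG_kcal = 1.07)
  pair <- generate_coupled_pair(
    truth, mgc,
    generator_spec(truth, titration_protocol(), noise_sd_ucal = 0,
                   seed = 2, mode = "ternary", mg_constants = mgc))
  g_mg <- generate_isotherm(pair$mg)
  g_no <- generate_isotherm(pair$nomg)
  f <- fit_ternary(g_mg$sample, g_no$sample,
                   pair$mg$protocol, pair$nomg$protocol, mgc)
  kappa_app <- apparent_constant(K_EG, K_EMG, 100, mgc) /
    apparent_constant(K_EG, K_EMG, 0, mgc)
  expect_rel_equal(f$kappa, kappa_app, 1e-4)
})

consistent_square <- function(temp = 30) {
  # build a detailed-balance square from three free K and the closure
  K_x <- 35
  K_s <- 288
  K_xs <- 125
  K_sx <- K_s * K_xs / K_x
  tibble::tibble(
    edge = c("x_to_e", "x_to_es", "s_to_e", "s_to_ex"),
    Kb_mM = c(K_x, K_xs, K_s, K_sx),
    dH_kcal = c(-4.1, -3.8, -6.3, -6.3 + (-3.8) - (-4.1)),
    temperature_C = temp
  )
}

test_that("closure check passes consistent squares and localises violations", {
  sq <- consistent_square()
  rep0 <- cycle_closure_check(sq)
  expect_equal(rep0$ln_K_discrepancy, 0, tolerance = 1e-12)
  expect_equal(rep0$dh_discrepancy_kcal, 0, tolerance = 1e-12)
  expect_true(rep0$consistent)
  expect_equal(rep0$kappa_xy, rep0$kappa_yx, tolerance = 1e-12)

  # doubling one K shifts the ln-discrepancy by exactly ln 2
  sq2 <- sq
  sq2$Kb_mM[sq2$edge == "x_to_e"] <- 2 * sq2$Kb_mM[sq2$edge == "x_to_e"]
  rep2 <- cycle_closure_check(sq2)
  expect_equal(abs(rep2$ln_K_discrepancy), log(2), tolerance = 1e-12)
  expect_false(rep2$consistent)

  expect_error(cycle_closure_check(sq[1:3, ]), "exactly one row")
})

test_that("the published MgGDP/Sdo1 square is flagged as reciprocity-inconsistent", {
  # Measured edges at 30 degC: MgGDP binding the free GTPase (35 mM^-1)
  # and the Sdo1-bound GTPase (125 mM^-1); Sdo1 binding the free GTPase
  # (288 mM^-1). The accompanying text states that MgGDP decreases the
  # Sdo1 interaction three-fold, i.e. K(s_to_ex) ~ 288/3 -- which cannot
  # close the square whose measured kappa is 125/35 ~ 3.6.
  sq <- tibble::tibble(
    edge = c("x_to_e", "x_to_es", "s_to_e", "s_to_ex"),
    Kb_mM = c(35, 125, 288, 288 / 3),
    dH_kcal = c(-4.1, -3.8, -6.3, -6.0),
    temperature_C = 30
  )
  rep <- cycle_closure_check(sq, tolerance = 0.2)
  expect_false(rep$consistent)
  expect_gt(abs(rep$ln_K_discrepancy), 2)
  expect_gt(rep$kappa_xy, 3)   # enhancement by one path
  expect_lt(rep$kappa_yx, 0.5) # suppression by the other
})

test_that("cooperativity table joins the cycle spec at shared temperatures", {
  fx <- load_efl1_fixtures()
  tab <- cooperativity_table(fx$params, fx$cycles, fx$constants)
  expect_equal(nrow(tab), 24) # 8 effects x 3 temperatures
  row <- dplyr::filter(tab, effect_label == "Mg-on-GTP (free)",
                       temperature_C == 30)
  expect_equal(row$kappa, 64 / 156)
  missing_cycle <- tibble::tibble(
    effect_label = "ghost", numerator_complex = "nope",
    denominator_complex = "R1086Q.GTP")
  expect_warning(out <- cooperativity_table(fx$params, missing_cycle),
                 "missing")
  expect_equal(nrow(out), 0)
})
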