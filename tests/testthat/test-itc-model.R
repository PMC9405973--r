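# Forward model of per-injection heats: oracle agreement, heat
# conservation, partition invariance, the Wiseman limit, and blank
# subtraction.

test_that("zero enthalpy and zero-ligand protocols give zero heats", {
  proto <- titration_protocol()
  iso <- predict_injection_heats(proto, list(n = 1, Kb_mM = 64,
                                             dH_kcal = 0))
  expect_equal(iso$Q_ucal, rep(0, 19))
  expect_warning(
    iso0 <- predict_injection_heats(
      titration_protocol(syringe_mM = 0),
      list(n = 1, Kb_mM = 64, dH_kcal = 1.07)),
    "zero")
  expect_equal(iso0$Q_ucal, rep(0, 19))
  expect_true(all(diff(iso$molar_ratio) > 0))
})

test_that("per-injection heats match the independent bisection/trapezoid oracle", {
  proto <- titration_protocol(cell_volume_uL = 200,
                              injection_volumes_uL = rep(2, 19),
                              syringe_mM = 2, cell_uM = 40,
                              temperature_C = 30)
  iso <- predict_injection_heats(
    proto, list(n = 1, Kb_mM = 1000 / 16, dH_kcal = 1.07))
  oracle <- oracle_onesite_heats(proto, 1, 1000 / 16, 1.07)
  expect_rel_equal(iso$ndh_kcal_per_mol, oracle, 1e-8)
})

test_that("total evolved heat at saturation equals n dH x cell protein moles", {
  for (case in list(list(n = 1, syringe_mM = 2.5),
                    list(n = 1.5, syringe_mM = 10))) {
    proto <- titration_protocol(syringe_mM = case$syringe_mM)
    iso <- predict_injection_heats(proto, list(n = case$n, Kb_mM = 1e6,
                                               dH_kcal = 1.07))
    total_kcal <- sum(iso$Q_ucal) * 1e-9
    expected <- case$n * 1.07 * (200e-6 * 40e-6)
    expect_lt(abs(total_kcal - expected) / expected, 0.01)
  }
})

test_that("cumulative heat is invariant to partitioning the injections", {
  params <- list(n = 1, Kb_mM = 64, dH_kcal = 1.07)
  base <- titration_protocol()
  merged <- titration_protocol(
    injection_volumes_uL = c(2, 2, 4, rep(2, 15)))
  q1 <- sum(predict_injection_heats(base, params)$Q_ucal)
  q2 <- sum(predict_injection_heats(merged, params)$Q_ucal)
  expect_lt(abs(q1 - q2) / abs(q1), 1e-9)
})

test_that("forward model approaches the Wiseman expression for small injections", {
  # one tiny injection on top of a pre-loaded cell approximates the
  # differential isotherm at that molar ratio
  dH <- 1.07
  Kb_mM <- 64
  E0 <- 40e-6
  c_value <- Kb_mM * 1000 * E0
  errs <- vapply(c(0.02, 0.005, 0.0005), function(dv_uL) {
    # equal injections up to molar ratio ~1 (the steepest region);
    # compare the last injection against the differential isotherm at
    # the injection's midpoint ratio. The huge cell and concentrated
    # syringe make dilution negligible (the Wiseman expression assumes
    # a fixed protein total).
    n_inj <- round(0.08 / dv_uL)
    proto <- titration_protocol(
      injection_volumes_uL = rep(dv_uL, n_inj),
      cell_volume_uL = 20000,
      syringe_mM = 1e4, cell_uM = 40)
    iso <- predict_injection_heats(proto,
                                   list(n = 1, Kb_mM = Kb_mM, dH_kcal = dH))
    i <- nrow(iso)
    mid <- (iso$molar_ratio[i] + iso$molar_ratio[i - 1]) / 2
    ref <- wiseman_ndh(mid, c_value, dH)
    abs(iso$ndh_kcal_per_mol[i] - ref) / abs(ref)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))   # error shrinks with injection size
  expect_lt(errs[3], 1e-3)
})

test_that("blank subtraction is pointwise and validates the schedule", {
  proto <- titration_protocol()
  sp <- generator_spec(list(n = 1, Kb_mM = 64, dH_kcal = 1.07), proto,
                       noise_sd_ucal = 0, blank_offset_ucal = 0.2,
                       seed = 1)
  g <- generate_isotherm(sp)
  clean <- predict_injection_heats(proto,
                                   list(n = 1, Kb_mM = 64, dH_kcal = 1.07))
  corrected <- subtract_dilution(g$sample, g$blank)
  expect_equal(corrected$Q_ucal, clean$Q_ucal, tolerance = 1e-9)
  expect_true(attr(corrected, "blank_subtracted"))
  # blank of zeros is the identity
  zero_blank <- g$blank
  zero_blank$Q_ucal <- rep(0, nrow(zero_blank))
  expect_equal(subtract_dilution(g$sample, zero_blank)$Q_ucal,
               g$sample$Q_ucal)
  # sample equal to blank cancels
  expect_equal(subtract_dilution(g$blank, g$blank)$Q_ucal,
               rep(0, nrow(g$blank)))
  short <- g$blank[1:10, ]
  expect_error(subtract_dilution(g$sample, short), "schedule")
})

test_that("isotherm CSV writer and reader round trip", {
  proto <- titration_protocol()
  iso <- predict_injection_heats(proto, list(n = 1, Kb_mM = 64,
                                             dH_kcal = 1.07))
  path <- withr::local_tempfile(fileext = ".csv")
  write_isotherm_csv(iso, path)
  back <- read_isotherm_csv(path)
  expect_equal(back$Q_ucal, iso$Q_ucal)
  expect_equal(back$molar_ratio, iso$molar_ratio)
})
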