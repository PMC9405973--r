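# Nonlinear fitting: self-consistency, scale consistency, cross-model
# agreement with the apparent constant, and the ternary joint fit.

test_that("one-site fit recovers noise-free truth to 1e-6 relative", {
  proto <- titration_protocol()
  truth <- list(n = 1, Kb_mM = 64, dH_kcal = 1.07)
  iso <- predict_injection_heats(proto, truth, mode = "one_site")
  f <- fit_one_site(iso, proto)
  est <- stats::setNames(f$estimates$estimate, f$estimates$term)
  expect_rel_equal(est[["n"]], 1, 1e-6)
  expect_rel_equal(est[["Kb_mM"]], 64, 1e-6)
  expect_rel_equal(est[["dH_kcal"]], 1.07, 1e-6)
})

test_that("fitting is scale-consistent in the heat axis", {
  proto <- titration_protocol()
  sp <- generator_spec(list(n = 1, Kb_mM = 64, dH_kcal = 1.07), proto,
                       noise_sd_ucal = 0.05, seed = 5)
  iso <- generate_isotherm(sp)$sample
  scaled <- iso
  scaled$Q_ucal <- iso$Q_ucal * 3
  scaled$ndh_kcal_per_mol <- iso$ndh_kcal_per_mol * 3
  # with the stoichiometry pinned the optimum transforms exactly
  f1 <- fit_one_site(iso, proto, fix_n = 1)
  e1 <- stats::setNames(f1$estimates$estimate, f1$estimates$term)
  f2 <- fit_one_site(scaled, proto, fix_n = 1,
                     init = list(Kb_mM = e1[["Kb_mM"]],
                                 dH_kcal = 3 * e1[["dH_kcal"]]))
  e2 <- stats::setNames(f2$estimates$estimate, f2$estimates$term)
  expect_rel_equal(e2[["Kb_mM"]], e1[["Kb_mM"]], 1e-8)
  expect_rel_equal(e2[["dH_kcal"]], 3 * e1[["dH_kcal"]], 1e-8)
  # with n floated the (n, K, dH) correlation leaves an optimizer floor
  g1 <- fit_one_site(iso, proto)
  d1 <- stats::setNames(g1$estimates$estimate, g1$estimates$term)
  g2 <- fit_one_site(scaled, proto,
                     init = list(n = d1[["n"]], Kb_mM = d1[["Kb_mM"]],
                                 dH_kcal = 3 * d1[["dH_kcal"]]))
  d2 <- stats::setNames(g2$estimates$estimate, g2$estimates$term)
  expect_rel_equal(d2[["Kb_mM"]], d1[["Kb_mM"]], 1e-5)
  expect_rel_equal(d2[["dH_kcal"]], 3 * d1[["dH_kcal"]], 1e-5)
})

test_that("low c-value triggers the identifiability warning", {
  proto <- titration_protocol(cell_uM = 0.5, syringe_mM = 0.05)
  iso <- predict_injection_heats(proto,
                                 list(n = 1, Kb_mM = 0.1, dH_kcal = -5))
  expect_warning(fit_one_site(iso, proto, fix_n = 1), "c-value")
})

test_that("one-site fit of a ternary isotherm returns the apparent constant", {
  mgc <- mg_constants(K_MgG = 1e4, K_Mg2G = 0)
  proto <- titration_protocol(total_Mg_mM = 5)
  truth <- list(n = 1, K_EG = 1.56e5, K_EMG = 6.4e4,
                dH_EG_kcal = 1.7, dH_EMG_kcal = 1.07)
  iso <- predict_injection_heats(proto, truth, mode = "ternary",
                                 mg_constants = mgc)
  f <- fit_one_site(iso, proto, fix_n = 1)
  K_hat <- f$estimates$estimate[f$estimates$term == "Kb_mM"] * 1000
  K_app <- apparent_constant(1.56e5, 6.4e4, 5e-3, mgc)
  expect_lt(abs(K_hat - K_app) / K_app, 0.05)
})

test_that("ternary joint fit round trips noise-free truth to 1e-4", {
  mgc <- mg_constants(K_MgG = 1e4, K_Mg2G = 0)
  truth <- list(n = 1, K_EG = 1.56e5, K_EMG = 6.4e4,
                dH_EG_kcal = 1.7, dH_EMG_kcal = 1.07)
  pair <- generate_coupled_pair(
    truth, mgc,
    generator_spec(truth, titration_protocol(), noise_sd_ucal = 0,
                   seed = 1, mode = "ternary", mg_constants = mgc))
  g_mg <- generate_isotherm(pair$mg)
  g_no <- generate_isotherm(pair$nomg)
  f <- fit_ternary(g_mg$sample, g_no$sample,
                   pair$mg$protocol, pair$nomg$protocol, mgc)
  est <- stats::setNames(f$estimates$estimate, f$estimates$term)
  expect_rel_equal(est[["K_EG"]], truth$K_EG, 1e-4)
  expect_rel_equal(est[["K_EMG"]], truth$K_EMG, 1e-4)
  expect_rel_equal(est[["dH_EG_kcal"]], truth$dH_EG_kcal, 1e-4)
  expect_rel_equal(est[["dH_EMG_kcal"]], truth$dH_EMG_kcal, 1e-4)
  expect_rel_equal(f$kappa, truth$K_EMG / truth$K_EG, 1e-4)
})

test_that("ternary fit validates its inputs", {
  mgc <- mg_constants(K_MgG = 1e4)
  proto1 <- titration_protocol(total_Mg_mM = 5, temperature_C = 30)
  proto2 <- titration_protocol(total_Mg_mM = 0, temperature_C = 25)
  truth <- list(n = 1, K_EG = 1e5, K_EMG = 5e4,
                dH_EG_kcal = 1, dH_EMG_kcal = 2)
  iso <- predict_injection_heats(proto1, truth, mode = "ternary",
                                 mg_constants = mgc)
  expect_error(fit_ternary(iso, iso, proto1, proto2, mgc), "temperature")
  proto3 <- titration_protocol(total_Mg_mM = 5)
  expect_error(fit_ternary(iso, iso, proto1, proto3, mgc),
               "rank-deficient")
})

test_that("both-metal-free pair degenerates to the one-site K_EG fit", {
  mgc <- mg_constants(K_MgG = 1e4)
  proto <- titration_protocol(total_Mg_mM = 0)
  truth <- list(n = 1, K_EG = 1.56e5, K_EMG = 6.4e4,
                dH_EG_kcal = 1.7, dH_EMG_kcal = 1.07)
  iso <- predict_injection_heats(proto, truth, mode = "ternary",
                                 mg_constants = mgc)
  expect_message(
    f <- fit_ternary(iso, iso, proto, proto, mgc),
    "metal-free")
  est <- stats::setNames(f$estimates$estimate, f$estimates$term)
  expect_rel_equal(est[["K_EG"]], truth$K_EG, 1e-5)
  expect_true(is.na(est[["K_EMG"]]))
  ref <- fit_one_site(iso, proto, fix_n = 1)
  expect_rel_equal(est[["K_EG"]],
                   ref$estimates$estimate[ref$estimates$term == "Kb_mM"] *
                     1000, 1e-9)
})

test_that("tidy, glance and autoplot work on fit objects", {
  proto <- titration_protocol()
  iso <- predict_injection_heats(proto,
                                 list(n = 1, Kb_mM = 64, dH_kcal = 1.07))
  f <- fit_one_site(iso, proto)
  td <- generics::tidy(f)
  expect_named(td, c("term", "estimate", "std_error"))
  gl <- generics::glance(f)
  expect_true(is.numeric(gl$c_value))
  p <- ggplot2::autoplot(f)
  expect_s3_class(p, "ggplot")
  expect_s3_class(ggplot2::autoplot(iso), "ggplot")
})
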