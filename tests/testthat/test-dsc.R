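# DSC two-state analysis: model, baseline, integration, fit,
# reversibility, cooperativity ratio.

R_GAS <- 8.314462618e-3

test_that("excess_cp_model midpoint value and normalization", {
  # at T = T_d, K = 1 and Cp = dHcal*dHvH / (4 R T^2)
  for (p in list(c(66.57, 432.2, 448.5), c(55, 300, 600))) {
    expect_equal(excess_cp_model(p[1], p[1], p[2], p[3]),
                 p[2] * p[3] / (4 * R_GAS * (p[1] + 273.15)^2),
                 tolerance = 1e-12)
  }
  expect_fm_error(excess_cp_model(50, 60, -1, 400), "fm_domain_error")
})

test_that("model integrates to dH_cal for random parameter draws", {
  set.seed(42)
  for (i in 1:8) {
    T_d <- runif(1, 45, 80)
    dH_cal <- runif(1, 150, 600)
    dH_vH <- runif(1, 150, 600)
    Tg <- seq(T_d - 35, T_d + 35, by = 0.02)
    integral <- trapz(Tg, excess_cp_model(Tg, T_d, dH_cal, dH_vH))
    expect_equal(integral, dH_cal, tolerance = 0.01 * dH_cal)
  }
})

test_that("peak width shrinks monotonically as dH_vH grows", {
  Tg <- seq(20, 100, by = 0.02)
  fwhm <- function(dH_vH) {
    cp <- excess_cp_model(Tg, 60, 400, dH_vH)
    above <- Tg[cp >= max(cp) / 2]
    diff(range(above))
  }
  widths <- vapply(c(200, 300, 450, 600, 900), fwhm, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("baseline subtraction recovers the model curve", {
  tg_pure <- gen_thermogram(thermogram_sim_spec())
  sub <- subtract_baseline(tg_pure)
  # pure model curve is essentially unchanged (window tails are ~1e-4
  # of the peak, so exact identity is impossible on a finite bracket)
  expect_lt(max(abs(sub$Cp - tg_pure$Cp)), 0.01 * max(tg_pure$Cp))
  # known tilt line is removed
  tg_tilt <- gen_thermogram(thermogram_sim_spec(
    baseline_coeffs = c(5, 0.03)))
  sub2 <- subtract_baseline(tg_tilt)
  expect_lt(max(abs(sub2$Cp - tg_pure$Cp)), 0.01 * max(tg_pure$Cp))
  # linear method on a tilt-only baseline
  sub3 <- subtract_baseline(tg_tilt, method = "linear")
  expect_lt(max(abs(sub3$Cp - tg_pure$Cp)), 0.02 * max(tg_pure$Cp))
  # all-zero input passes through
  z <- thermogram(seq(25, 110, 0.5), rep(0, 171))
  expect_equal(subtract_baseline(z)$Cp, rep(0, 171))
  expect_true(subtract_baseline(tg_tilt)$baseline_subtracted)
})

test_that("integrate_enthalpy is the trapezoidal integral", {
  spec <- thermogram_sim_spec(T_d = 66.57, dH_cal = 432.2, dH_vH = 448.5)
  tg <- gen_thermogram(spec)
  expect_equal(integrate_enthalpy(tg), 432.2, tolerance = 0.01 * 432.2)
  z <- thermogram(seq(25, 110, 0.5), rep(0, 171))
  expect_equal(integrate_enthalpy(z), 0)
  tg2 <- thermogram(tg$T_c, 2 * tg$Cp)
  expect_equal(integrate_enthalpy(tg2), 2 * integrate_enthalpy(tg),
               tolerance = 1e-12)
})

test_that("two-state fit round-trips generator parameters", {
  # noiseless: parameters recovered to <= 0.1%
  for (p in list(c(66.57, 432.2, 448.5), c(60.38, 307.7, 412.9))) {
    tg <- subtract_baseline(gen_thermogram(thermogram_sim_spec(
      T_d = p[1], dH_cal = p[2], dH_vH = p[3])))
    fit <- fit_two_state(tg)
    expect_equal(fit$T_d, p[1], tolerance = 1e-3 * p[1])
    expect_equal(fit$dH_cal, p[2], tolerance = 1e-3 * p[2])
    expect_equal(fit$dH_vH, p[3], tolerance = 1e-3 * p[3])
    expect_identical(fit$ratio, fit$dH_vH / fit$dH_cal)
  }
  # equal enthalpies give a cooperativity ratio of 1
  tg_eq <- subtract_baseline(gen_thermogram(thermogram_sim_spec(
    T_d = 62, dH_cal = 380, dH_vH = 380)))
  expect_equal(fit_two_state(tg_eq)$ratio, 1.00, tolerance = 0.01)
})

test_that("noisy thermogram still localizes the transition", {
  spec <- thermogram_sim_spec(noise_sd = 0.01 * 55, seed = 17,
                              baseline_coeffs = c(2, 0.01))
  fit <- fit_two_state(subtract_baseline(gen_thermogram(spec)))
  expect_lt(abs(fit$T_d - 66.57), 0.1)
})

test_that("fit is stable under grid refinement", {
  coarse <- thermogram_sim_spec(T_grid = seq(25, 110, by = 0.1))
  fine <- thermogram_sim_spec(T_grid = seq(25, 110, by = 0.05))
  f1 <- fit_two_state(subtract_baseline(gen_thermogram(coarse)))
  f2 <- fit_two_state(subtract_baseline(gen_thermogram(fine)))
  expect_equal(f1$dH_vH / f1$dH_cal, f2$dH_vH / f2$dH_cal,
               tolerance = 1e-4)
})

test_that("enthalpy_ratio reproduces tabulated cooperativity values", {
  expect_equal(round(enthalpy_ratio(399.90, 512.60), 2), 1.28)
  expect_equal(round(enthalpy_ratio(307.70, 412.90), 2), 1.34)
  expect_equal(enthalpy_ratio(123.4, 123.4), 1.0)
  expect_fm_error(enthalpy_ratio(0, 400), "fm_domain_error")
})

test_that("reversibility compares scan enthalpies", {
  tg <- subtract_baseline(gen_thermogram(thermogram_sim_spec()))
  expect_equal(reversibility(tg, tg), 100)
  tg2 <- thermogram(tg$T_c, 0.98 * tg$Cp, scan_index = 2L)
  expect_equal(reversibility(tg, tg2), 98, tolerance = 1e-9)
  zero <- thermogram(tg$T_c, rep(0, length(tg$T_c)), scan_index = 2L)
  expect_equal(reversibility(tg, zero), 0)
  expect_fm_error(reversibility(zero, tg), "fm_domain_error")
})
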