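# Generators: sigmoidal traces, two-state thermograms, AFM topographies.

test_that("gen_kinetic_trace evaluates the Boltzmann sigmoid exactly", {
  spec <- kinetic_sim_spec(y1 = 0, y2 = 100, t_lag = 64.80, t_half = 80.30,
                           t_grid = c(0, 50, 64.80, 80.30, 150, 1000),
                           noise_sd = 0)
  tr <- gen_kinetic_trace(spec)
  # midpoint forced by the model
  expect_equal(tr$y[tr$t == 80.30], 50.0, tolerance = 1e-12)
  # at t = t_lag the sigmoid sits at y1 + (y2-y1)/(1+e^2)
  expect_equal(tr$y[tr$t == 64.80], 100 / (1 + exp(2)), tolerance = 1e-12)
  expect_equal(100 / (1 + exp(2)), 11.920292, tolerance = 1e-6)
  # far beyond the transition the signal approaches the plateau
  expect_equal(tr$y[tr$t == 1000], 100, tolerance = 1e-6)
  # noiseless trace satisfies the closed form at every grid point
  expect_equal(tr$y,
               boltzmann_curve(tr$t, 0, 100, 80.30, 64.80),
               tolerance = 1e-15)
})

test_that("kinetic spec validation and reproducibility", {
  expect_fm_error(kinetic_sim_spec(t_lag = 10, t_half = 10),
                  "fm_invalid_spec")
  expect_fm_error(kinetic_sim_spec(t_grid = c(1, 1, 2)), "fm_invalid_spec")
  expect_fm_error(kinetic_sim_spec(noise_sd = -1), "fm_invalid_spec")
  s <- kinetic_sim_spec(noise_sd = 3, seed = 11L)
  expect_identical(gen_kinetic_trace(s)$y, gen_kinetic_trace(s)$y)
  s2 <- kinetic_sim_spec(noise_sd = 3, seed = 12L)
  expect_false(identical(gen_kinetic_trace(s)$y, gen_kinetic_trace(s2)$y))
})

test_that("gen_thermogram integral and peak position match the model", {
  spec <- thermogram_sim_spec(T_d = 66.57, dH_cal = 432.2, dH_vH = 448.5)
  tg <- gen_thermogram(spec)
  # excess heat capacity integrates to dH_cal
  expect_equal(integrate_enthalpy(tg), 432.2, tolerance = 0.01)
  # with equal enthalpies the maximum sits at T_d
  tg2 <- gen_thermogram(thermogram_sim_spec(T_d = 60, dH_cal = 400,
                                            dH_vH = 400))
  expect_equal(tg2$T_c[which.max(tg2$Cp)], 60, tolerance = 0.1)
  # transition is localized: far from T_d the signal vanishes
  expect_lt(max(abs(tg$Cp[tg$T_c < 40])), 1e-3)
  expect_fm_error(
    thermogram_sim_spec(T_d = 100, T_grid = seq(25, 110, 0.5)),
    "fm_invalid_spec")
})

test_that("thermogram generator is reproducible and baseline additive", {
  s <- thermogram_sim_spec(noise_sd = 0.3, seed = 4L)
  expect_identical(gen_thermogram(s)$Cp, gen_thermogram(s)$Cp)
  s_base <- thermogram_sim_spec(baseline_coeffs = c(1, 0.02))
  tg <- gen_thermogram(s_base)
  tg0 <- gen_thermogram(thermogram_sim_spec())
  expect_equal(tg$Cp - tg0$Cp, 1 + 0.02 * tg$T_c, tolerance = 1e-12)
})

test_that("single noiseless fibril renders its drawn apex height", {
  sim <- gen_afm_image(afm_sim_spec(
    image_shape = c(128L, 128L),
    populations = list(c(3.7, 0, 1)),
    background = list(tilt = c(0, 0), bow = 0, roughness_sd = 0),
    between_fraction = 1, fibril_length = c(150, 250), seed = 7))
  expect_equal(max(sim$map$heights), 3.7, tolerance = 0.01 * 3.7)
  expect_length(sim$truth$fibrils, 1L)
  expect_equal(sim$truth$fibrils[[1]]$height, 3.7)
})

test_that("drawn population means follow the stated mixture", {
  spec <- afm_sim_spec(seed = 3)
  sim <- gen_afm_image(spec)
  h <- vapply(sim$truth$fibrils, `[[`, numeric(1), "height")
  pop <- vapply(sim$truth$fibrils, `[[`, numeric(1), "population")
  for (k in 1:3) {
    p <- spec$populations[[k]]
    sd_between <- sqrt(spec$between_fraction) * p["sd"]
    se <- sd_between / sqrt(p["count"])
    expect_lt(abs(mean(h[pop == k]) - p["mean"]), 2 * se + 1e-9)
    expect_equal(sum(pop == k), unname(p["count"]))
  }
})

test_that("centerlines respect the minimum separation", {
  sim <- gen_afm_image(afm_sim_spec(
    image_shape = c(256L, 256L),
    populations = list(c(3, 0.3, 6), c(5, 0.5, 6)),
    min_separation = 24, fibril_length = c(150, 300), seed = 5))
  pts <- lapply(sim$truth$fibrils, `[[`, "points")
  sep_px <- 24 / 4
  for (i in seq_along(pts)) {
    for (j in seq_len(i - 1L)) {
      d2 <- outer(pts[[i]][, 1], pts[[j]][, 1], `-`)^2 +
        outer(pts[[i]][, 2], pts[[j]][, 2], `-`)^2
      expect_gte(sqrt(min(d2)), sep_px)
    }
  }
})

test_that("ground-truth local heights are readable off the clean surface", {
  sim <- gen_afm_image(afm_sim_spec(seed = 6))
  for (f in sim$truth$fibrils[seq(1, 180, by = 23)]) {
    idx <- cbind(round(f$points[, 1]), round(f$points[, 2]))
    looked_up <- sim$truth$clean[idx]
    # interior points (away from the tapering rounding at the very ends);
    # the nearest-pixel lookup sits below the apex by at most
    # 1 - exp(-0.5^2 / (2 sigma_px^2)) of the local height (~8% worst
    # case, ~4% at the median pixel offset)
    core <- seq(10, nrow(idx) - 10)
    rel <- abs(looked_up[core] - f$height_profile[core]) /
      f$height_profile[core]
    expect_lt(stats::median(rel), 0.06)
    expect_lt(stats::quantile(rel, 0.9), 0.15)
  }
})

test_that("AFM generator is bit-reproducible and fails loudly when full", {
  s <- afm_sim_spec(image_shape = c(128L, 128L),
                    populations = list(c(3, 0.3, 4)),
                    fibril_length = c(100, 200), seed = 9)
  expect_identical(gen_afm_image(s)$map$heights,
                   gen_afm_image(s)$map$heights)
  packed <- afm_sim_spec(image_shape = c(64L, 64L),
                         populations = list(c(3, 0.3, 400)),
                         min_separation = 40, seed = 1)
  expect_fm_error(gen_afm_image(packed, max_tries = 5L),
                  "fm_placement_error")
})
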