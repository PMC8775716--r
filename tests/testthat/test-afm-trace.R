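# Ridge tracing, normal estimation, cross-section profiles, Gaussian
# profile fits.

test_that("automatic tracing follows a straight fibril centerline", {
  m <- straight_fibril_map(row = 32, h = 3.7)
  paths <- trace_ridges(m)
  expect_length(paths, 1L)
  p <- paths[[1]]
  rms <- sqrt(mean((p$points[, 1] - 32)^2))
  expect_lt(rms, 1)
  expect_false(any(p$excluded))
})

test_that("seeded live-wire finds the ridge between endpoints", {
  m <- straight_fibril_map(row = 20, h = 5)
  paths <- trace_ridges(m, seeds = list(rbind(c(20, 6), c(20, 58))))
  expect_length(paths, 1L)
  expect_lt(sqrt(mean((paths[[1]]$points[, 1] - 20)^2)), 1)
  expect_fm_error(
    trace_ridges(m, seeds = list(rbind(c(3, 3), c(20, 58)))),
    "fm_tracing_error")
})

test_that("crossing fibrils are flagged excluded near the intersection", {
  nr <- 64
  H <- matrix(0, nr, nr)
  d1 <- outer(seq_len(nr), seq_len(nr),
              function(r, c) abs(r - 32))            # horizontal ridge
  d2 <- outer(seq_len(nr), seq_len(nr),
              function(r, c) abs(c - 32))            # vertical ridge
  H <- pmax(3.7 * exp(-d1^2 / (2 * 1.5^2)), 3.7 * exp(-d2^2 / (2 * 1.5^2)))
  m <- height_map(H, 4, flattened = TRUE)
  paths <- trace_ridges(m)
  expect_gte(length(paths), 2L)
  # points close to the junction carry the exclusion flag
  near_junction_excluded <- vapply(paths, function(p) {
    d <- sqrt((p$points[, 1] - 32)^2 + (p$points[, 2] - 32)^2)
    any(p$excluded[d < 4])
  }, logical(1))
  expect_true(any(near_junction_excluded))
})

test_that("blank maps give zero paths with a warning", {
  m <- height_map(matrix(0, 64, 64), 4, flattened = TRUE)
  expect_warning(paths <- trace_ridges(m), "zero paths")
  expect_length(paths, 0L)
})

test_that("estimate_normals handles lines, arcs and outliers", {
  # straight horizontal path: all normals vertical
  p <- ridge_path(cbind(rep(10, 30), 1:30))
  n <- estimate_normals(p)
  expect_equal(abs(n[, 1]), rep(1, 30), tolerance = 1e-12)
  expect_equal(n[, 2], rep(0, 30), tolerance = 1e-12)
  # circular arc: normals align with the radius direction within 3 deg
  theta <- seq(0, pi / 2, length.out = 60)
  arc <- ridge_path(cbind(40 - 30 * sin(theta), 10 + 30 * cos(theta)))
  nn <- estimate_normals(arc)
  radial <- cbind(arc$points[, 1] - 40, arc$points[, 2] - 10) / 30
  ang <- acos(pmin(abs(rowSums(nn * radial)), 1)) * 180 / pi
  expect_lt(max(ang[5:55]), 3)
  # a single outlier point does not corrupt neighboring tangents
  pts <- cbind(rep(10, 21), 1:21)
  pts[11, 1] <- 11.5
  n_out <- estimate_normals(ridge_path(pts), window = 5)
  expect_equal(abs(n_out[c(9, 13), 1]), c(1, 1), tolerance = 1e-9)
  expect_fm_error(estimate_normals(ridge_path(cbind(1:3, 1:3))),
                  "fm_invalid_spec")
})

test_that("extract_profiles samples symmetric subpixel cross-sections", {
  m <- straight_fibril_map(row = 32, h = 3.7, sigma_px = 1.5)
  paths <- trace_ridges(m)
  p <- paths[[1]]
  normals <- estimate_normals(p)
  profs <- extract_profiles(p, normals, m, half_width = 20)
  expect_equal(length(profs) + attr(profs, "n_skipped"),
               nrow(p$points))
  pr <- profs[[5]]
  expect_true(length(pr$offsets) %% 2 == 1)
  expect_equal(pr$offsets, -rev(pr$offsets))
  # noiseless fibril: profile apex matches the rendered apex at offset 0
  expect_equal(max(pr$heights), 3.7, tolerance = 0.02 * 3.7)
  expect_equal(pr$offsets[which.max(pr$heights)], 0, tolerance = 2)
  expect_fm_error(extract_profiles(p, normals, m, half_width = 4),
                  "fm_invalid_spec")
})

test_that("profiles at excluded points are skipped", {
  m <- straight_fibril_map(row = 32, h = 3.7)
  p <- trace_ridges(m)[[1]]
  p$excluded[1:5] <- TRUE
  profs <- extract_profiles(p, estimate_normals(p), m)
  expect_gte(attr(profs, "n_skipped"), 5L)
})

test_that("fit_profile recovers exact Gaussian parameters", {
  pr <- gaussian_profile(amplitude = 3.7, baseline = 0.2, width = 5)
  fit <- fit_profile(pr)
  expect_true(fit$accepted)
  expect_equal(fit$amplitude, 3.7, tolerance = 1e-4)
  expect_equal(fit$baseline, 0.2, tolerance = 1e-4)
  expect_equal(fit$r, 1.0, tolerance = 1e-9)
})

test_that("pure-noise profiles are rejected, not errored", {
  set.seed(33)
  n_rej <- 0L
  for (i in 1:10) {
    pr <- gaussian_profile(amplitude = 0, baseline = 0, noise_sd = 0.2)
    pr$heights <- rnorm(length(pr$offsets), 0, 0.2)
    f <- fit_profile(pr)
    if (!f$accepted) n_rej <- n_rej + 1L
  }
  expect_gte(n_rej, 9L)
})

test_that("off-center peaks fail the central-third acceptance rule", {
  pr <- gaussian_profile(position = 15, half_width = 20)
  f <- fit_profile(pr)
  expect_false(f$accepted)
  expect_gt(f$r, 0.95)   # rejected on position, not on fit quality
})

test_that("profile fits on rough synthetic fibrils track truth heights", {
  sim <- gen_afm_image(afm_sim_spec(
    image_shape = c(192L, 192L), populations = list(c(3.7, 0, 6)),
    background = list(tilt = c(8, 5), bow = 1, roughness_sd = 0.15),
    between_fraction = 1, fibril_length = c(120, 250), seed = 14))
  flat <- flatten_scanlines(sim$map)
  amps <- c()
  for (p in trace_ridges(flat)) {
    if (nrow(p$points) < 5) next
    profs <- extract_profiles(p, estimate_normals(p), flat)
    for (pr in profs) {
      f <- fit_profile(pr)
      if (isTRUE(f$accepted)) amps <- c(amps, f$amplitude)
    }
  }
  expect_gt(length(amps), 100)
  expect_lt(abs(stats::median(amps) - 3.7), 0.2)
})
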