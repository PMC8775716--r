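# Height histograms, multi-peak decomposition, hierarchical assembly.

test_that("build_histogram bookkeeping", {
  set.seed(2)
  vals <- rnorm(1600, 3.7, 0.5)
  hg <- histogram_from_values(vals)
  expect_equal(sum(hg$counts), 1600)
  expect_equal(hg$n_profiles, 1600)
  expect_equal(diff(hg$breaks), rep(0.25, length(hg$counts)),
               tolerance = 1e-12)
  # single repeated value occupies one bin
  hg1 <- histogram_from_values(rep(2.6, 50))
  expect_equal(sum(hg1$counts > 0), 1L)
  # halving the bin width conserves the total count
  hg2 <- histogram_from_values(vals, bin_width = 0.125)
  expect_equal(sum(hg2$counts), 1600)
  # rejected fits are not counted
  fits <- list(structure(list(amplitude = 3, accepted = TRUE, r = 1),
                         class = "profile_fit"),
               structure(list(amplitude = 9, accepted = FALSE, r = 0.5),
                         class = "profile_fit"))
  expect_warning(hb <- build_histogram(fits), "unstable")
  expect_equal(hb$n_profiles, 1L)
  expect_fm_error(build_histogram(list()), "fm_invalid_spec")
})

test_that("two well-separated components are recovered", {
  set.seed(9)
  vals <- c(rnorm(800, 3.7, 0.4), rnorm(800, 6.1, 0.5))
  fit <- fit_multipeak(histogram_from_values(vals))
  expect_equal(fit$n_peaks, 2L)
  expect_equal(fit$peaks$mean, c(3.7, 6.1), tolerance = 0.2 / 3.7)
})

test_that("single-component histograms select one peak", {
  set.seed(10)
  fit <- fit_multipeak(histogram_from_values(rnorm(1000, 4.5, 0.6)))
  expect_equal(fit$n_peaks, 1L)
  expect_equal(fit$peaks$mean, 4.5, tolerance = 0.05)
})

test_that("the three-population mixture is decomposed from iid draws", {
  set.seed(5)
  vals <- c(rnorm(1300, 2.6, 0.4), rnorm(1300, 3.7, 0.8),
            rnorm(1300, 6.1, 1.1))
  fit <- fit_multipeak(histogram_from_values(vals))
  expect_equal(fit$n_peaks, 3L)
  expect_lt(max(abs(fit$peaks$mean - c(2.6, 3.7, 6.1))), 0.3)
  expect_true(all(diff(fit$peaks$mean) > 0))
})

test_that("near-coincident components are merged with a warning", {
  set.seed(6)
  vals <- rnorm(1800, 4, 0.6)   # one hump, two components requested
  expect_warning(
    fit <- fit_multipeak(histogram_from_values(vals), n_peaks = 2),
    "merging")
  expect_equal(fit$n_peaks, 1L)
  expect_equal(fit$peaks$mean, 4, tolerance = 0.05)
})

test_that("degenerate histograms are rejected", {
  expect_fm_error(fit_multipeak(histogram_from_values(rep(3, 500))),
                  "fm_invalid_spec")
})

test_that("predict_heights implements the packing rules", {
  m <- assembly_model(2.6, "sqrt_n")
  expect_equal(unname(predict_heights(m, "1")), 2.6)
  expect_equal(unname(predict_heights(m, "1 + 1")), 2.6 * sqrt(2),
               tolerance = 1e-12)
  expect_equal(round(unname(predict_heights(m, "1 + 1")), 2), 3.68)
  add <- assembly_model(2.6, "additive")
  expect_equal(unname(predict_heights(add, "1 + 1")), 5.2)
  pyth <- assembly_model(2.6, "pythagorean")
  expect_equal(unname(predict_heights(pyth, "2 + 2")),
               unname(predict_heights(m, "2 + 2")), tolerance = 1e-12)
  expect_fm_error(predict_heights(m, "a + b"), "fm_parse_error")
  expect_fm_error(assembly_model(-1), "fm_domain_error")
})

test_that("predicted heights increase with protofilament count", {
  comps <- c("1", "1 + 1", "2 + 1", "2 + 2", "4 + 1", "4 + 2", "4 + 4",
             "8 + 1", "8 + 8")
  totals <- c(1, 2, 3, 4, 5, 6, 8, 9, 16)
  for (rule in c("sqrt_n", "pythagorean", "additive")) {
    h <- predict_heights(assembly_model(2.6, rule), comps)
    expect_true(all(diff(h[order(totals)]) > 0), info = rule)
  }
})

test_that("assign_fibril_types labels peaks by nearest prediction", {
  mk_mix <- function(means) {
    structure(list(peaks = data.frame(amplitude = rep(100, length(means)),
                                      mean = means,
                                      sd = rep(0.4, length(means))),
                   n_peaks = length(means), gof = 0.99),
              class = "peak_mixture_fit")
  }
  model <- assembly_model(2.6, "sqrt_n")
  cand <- c("1", "1 + 1", "2 + 1", "2 + 2", "4 + 4")
  a <- assign_fibril_types(mk_mix(c(2.6, 3.7)), model, cand)
  expect_equal(a$label, c("1", "1 + 1"))
  # 5.2 nm under sqrt_n with h1 = 2.6 is exactly a (2 + 2) fibril
  a2 <- assign_fibril_types(mk_mix(5.2), model, cand, tie_tol = 0.05)
  expect_equal(a2$label, "2 + 2")
  # sub-protofilament peaks are flagged
  expect_warning(
    a3 <- assign_fibril_types(mk_mix(1.0), model, cand),
    "below half")
  expect_equal(a3$label, "sub-protofilament")
  # near-ties report all candidate compositions
  a4 <- assign_fibril_types(mk_mix(5.55), model,
                            c("2 + 2", "4 + 1"), tie_tol = 0.4)
  expect_match(a4$label, "2 \\+ 2")
  expect_match(a4$label, "4 \\+ 1")
})
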