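# Shared fixture builders (everything generated in code; no data files).

# Flattened map holding one straight horizontal fibril along `row` with
# Gaussian cross-section (apex `h` nm, transverse sigma in px).
straight_fibril_map <- function(nr = 64, nc = 64, row = 32, h = 3.7,
                                sigma_px = 1.5, pixel_size = 4,
                                cols = 5:(nc - 5)) {
  H <- matrix(0, nr, nc)
  d <- (seq_len(nr) - row)
  prof <- h * exp(-d^2 / (2 * sigma_px^2))
  for (cc in cols) H[, cc] <- pmax(H[, cc], prof)
  height_map(H, pixel_size, flattened = TRUE)
}

# Height histogram straight from a numeric vector of ridge heights.
histogram_from_values <- function(values, bin_width = 0.25) {
  fits <- lapply(values, function(v) {
    structure(list(position = 0, width = 1, amplitude = v, baseline = 0,
                   r = 1, accepted = TRUE), class = "profile_fit")
  })
  suppressWarnings(build_histogram(fits, bin_width = bin_width))
}

# Synthetic cross-section profile: exact Gaussian plus optional noise.
gaussian_profile <- function(amplitude = 3.7, baseline = 0.2, position = 0,
                             width = 5, half_width = 20, step = 2,
                             noise_sd = 0, seed = NULL) {
  x <- seq(-half_width, half_width, by = step)
  y <- baseline + amplitude * exp(-(x - position)^2 / (2 * width^2))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(y), 0, noise_sd)
  }
  structure(list(offsets = x, heights = y, normal = c(1, 0), index = 1L),
            class = "cross_section_profile")
}

expect_fm_error <- function(expr, class) {
  expect_error(expr, class = class)
}
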