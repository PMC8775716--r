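# AFM height maps: container, bilinear sampling, per-scanline flattening.

#' AFM height map container
#'
#' A topography as a numeric matrix of heights in nm, row-major with the
#' origin at the top-left scanline (row 1 = first scanline), plus the
#' isotropic pixel size in nm/pixel.
#'
#' @param heights Numeric matrix (nm), finite, at least 64 x 64.
#' @param pixel_size Pixel size in nm/pixel, positive.
#' @param label Free text.
#' @param flattened Logical; set by [flatten_scanlines()].
#' @return Object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size, label = "", flattened = FALSE) {
  heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  if (any(!is.finite(heights)))
    fm_error("height map contains non-finite values", "fm_invalid_spec")
  if (nrow(heights) < 64L || ncol(heights) < 64L)
    fm_error("height map must be at least 64 x 64 pixels", "fm_invalid_spec")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    fm_error("pixel_size must be a positive scalar (nm/pixel)",
             "fm_invalid_spec")
  structure(list(heights = heights, pixel_size = as.numeric(pixel_size),
                 label = label, flattened = isTRUE(flattened)),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf(
    "<height_map> %s: %d x %d px @ %g nm/px, heights [%.3g, %.3g] nm%s\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    nrow(x$heights), ncol(x$heights), x$pixel_size,
    min(x$heights), max(x$heights),
    if (x$flattened) ", flattened" else ""))
  invisible(x)
}

#' Bilinear sampling of a height matrix at subpixel positions
#'
#' Samples `heights` at real-valued (row, col) positions by bilinear
#' interpolation. At integer lattice points the stored pixel value is
#' returned exactly. Positions must lie within `[1, nrow] x [1, ncol]`.
#'
#' @param heights Numeric matrix.
#' @param row,col Real-valued coordinates (vectors of equal length).
#' @return Interpolated values.
#' @export
bilinear_sample <- function(heights, row, col) {
  nr <- nrow(heights); nc <- ncol(heights)
  if (any(row < 1 | row > nr | col < 1 | col > nc))
    fm_error("sample position outside the image", "fm_out_of_bounds")
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  h00 <- heights[cbind(r0, c0)]
  h10 <- heights[cbind(r0 + 1L, c0)]
  h01 <- heights[cbind(r0, c0 + 1L)]
  h11 <- heights[cbind(r0 + 1L, c0 + 1L)]
  h00 * (1 - fr) * (1 - fc) + h10 * fr * (1 - fc) +
    h01 * (1 - fr) * fc + h11 * fr * fc
}

#' Per-scanline polynomial flattening
#'
#' Subtracts, from every scanline (row), the least-squares polynomial of
#' the given order fitted to background pixels. Fibril (foreground)
#' pixels are excluded by iterative robust masking: the polynomial is
#' fitted to all pixels, pixels whose residual exceeds `k_mad` robust
#' standard deviations above the line are masked, and the fit is
#' repeated. This removes plane tilt and per-scanline bow, the dominant
#' AFM background artifacts, while preserving ridge heights.
#'
#' @param map A [height_map()].
#' @param order Polynomial order per scanline, one of 0:3 (default 2).
#' @param k_mad Masking threshold in robust SDs (default 2).
#' @param iterations Mask-refit iterations (default 3).
#' @return Flattened `height_map` (per-line background median ~ 0).
#' @export
flatten_scanlines <- function(map, order = 2L, k_mad = 2, iterations = 3L) {
  stopifnot(inherits(map, "height_map"))
  if (!order %in% 0:3)
    fm_error("order must be one of 0, 1, 2, 3", "fm_invalid_spec")
  H <- map$heights
  nc <- ncol(H)
  x <- seq(-1, 1, length.out = nc)
  X <- stats::poly(x, degree = max(order, 1), raw = FALSE)
  X <- cbind(1, if (order >= 1) X[, seq_len(order), drop = FALSE])
  for (i in seq_len(nrow(H))) {
    yline <- H[i, ]
    mask <- rep(TRUE, nc)
    for (it in seq_len(iterations)) {
      if (sum(mask) < order + 2L)
        fm_error(sprintf(
          "scanline %d has fewer than %d background pixels", i, order + 2L),
          "fm_flattening_error")
      co <- stats::lm.fit(X[mask, , drop = FALSE], yline[mask])$coefficients
      co[is.na(co)] <- 0
      base <- drop(X %*% co)
      res <- yline - base
      s <- stats::mad(res[mask])
      if (s == 0) break
      mask <- res < k_mad * s   # one-sided: ridges protrude upward
    }
    H[i, ] <- yline - base - stats::median((yline - base)[mask])
  }
  height_map(H, map$pixel_size, label = map$label, flattened = TRUE)
}
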