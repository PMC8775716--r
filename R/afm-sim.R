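# Synthetic AFM topographies: curved non-crossing fibrils with Gaussian
# transverse profiles on a tilted, bowed, rough background, with full
# ground truth (centerlines + drawn ridge heights) for recovery tests.

#' Simulation spec for a synthetic AFM topography
#'
#' Fibril ridge heights are drawn from a normal mixture (one component
#' per population); each fibril is rendered as a smooth random curve
#' (cubic spline through 4-8 jittered waypoints with bounded curvature)
#' with a Gaussian transverse profile whose apex equals the drawn ridge
#' height. The background is a tilt plane plus an independent
#' second-order bow per scanline plus white Gaussian roughness -- exactly
#' the artifacts per-scanline polynomial flattening must remove. Tip
#' dilation is not simulated.
#'
#' @param image_shape Integer c(rows, cols) in pixels.
#' @param pixel_size nm per pixel (isotropic).
#' @param populations List of `c(mean, sd, count)` per fibril
#'   population: mean ridge height (nm), observed component SD (nm),
#'   number of fibrils. Defaults to the three-population protofilament /
#'   protofibril / fibril mixture (2.6 +/- 0.4, 3.7 +/- 0.8,
#'   6.1 +/- 1.1 nm). The SD is the width of the observed histogram
#'   component; `between_fraction` controls how much of its variance is
#'   between-fibril spread versus along-ridge fluctuation.
#' @param fibril_width `c(mean, sd)` of the transverse Gaussian sigma in
#'   nm.
#' @param background List with `tilt` (nm drop across rows/cols, length
#'   2), `bow` (per-scanline second-order bow amplitude SD, nm) and
#'   `roughness_sd` (white-noise SD, nm).
#' @param min_separation Minimum centerline-to-centerline distance in nm
#'   (0 disables the non-crossing constraint).
#' @param fibril_length `c(min, max)` fibril length in nm.
#' @param between_fraction Fraction of each population's height
#'   variance attributed to between-fibril spread; the remainder is
#'   smooth along-ridge modulation (correlation length ~30 nm). Fibril
#'   types in the hierarchical assembly have near-quantized heights, so
#'   most of the observed component width comes from structural
#'   fluctuation along the ridge and instrument precision, not from
#'   fibril-to-fibril spread (1 restores constant-height fibrils).
#' @param seed Integer seed; all randomness derives from it.
#' @return Object of class `afm_sim_spec`.
#' @export
afm_sim_spec <- function(image_shape = c(512L, 512L), pixel_size = 4,
                         populations = list(c(2.6, 0.4, 60),
                                            c(3.7, 0.8, 60),
                                            c(6.1, 1.1, 60)),
                         fibril_width = c(5, 0.5),
                         background = list(tilt = c(12, 8), bow = 2,
                                           roughness_sd = 0.15),
                         min_separation = 16, fibril_length = c(100, 300),
                         between_fraction = 0.25, seed = 1L) {
  pops <- lapply(populations, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L)
      fm_error("each population is c(mean, sd, count)", "fm_invalid_spec")
    if (p[1] <= 0) fm_error("population mean height must be > 0",
                            "fm_invalid_spec")
    if (p[2] < 0) fm_error("population SD must be >= 0", "fm_invalid_spec")
    if (p[3] < 1) fm_error("population count must be >= 1", "fm_invalid_spec")
    stats::setNames(p, c("mean", "sd", "count"))
  })
  bg <- utils::modifyList(list(tilt = c(0, 0), bow = 0, roughness_sd = 0),
                          background)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = as.numeric(pixel_size),
                 populations = pops,
                 fibril_width = as.numeric(fibril_width),
                 background = bg,
                 min_separation = as.numeric(min_separation),
                 fibril_length = as.numeric(fibril_length),
                 between_fraction = as.numeric(between_fraction),
                 seed = as.integer(seed)),
            class = "afm_sim_spec")
}

# Smooth random centerline: spline through waypoints laid down by a
# bounded-turn random walk. Returns dense subpixel points (row, col)
# spaced ~0.3 px, or NULL if the curve leaves the usable area.
random_centerline <- function(nr, nc, len_px, margin) {
  n_way <- sample(4:8, 1L)
  step <- len_px / (n_way - 1)
  heading <- stats::runif(1, 0, 2 * pi)
  pos <- c(stats::runif(1, margin, nr - margin),
           stats::runif(1, margin, nc - margin))
  pts <- matrix(NA_real_, n_way, 2)
  pts[1, ] <- pos
  for (k in 2:n_way) {
    heading <- heading + max(min(stats::rnorm(1, 0, 0.3), 0.5), -0.5)
    pos <- pos + step * c(sin(heading), cos(heading))
    pts[k, ] <- pos
  }
  if (any(pts[, 1] < margin | pts[, 1] > nr - margin |
          pts[, 2] < margin | pts[, 2] > nc - margin)) return(NULL)
  s <- seq_len(n_way)
  dense_s <- seq(1, n_way, length.out = max(ceiling(len_px / 0.3), 16L))
  cbind(stats::splinefun(s, pts[, 1], method = "natural")(dense_s),
        stats::splinefun(s, pts[, 2], method = "natural")(dense_s))
}

# Smooth mean-zero modulation along a path of n dense points: a natural
# spline through random knot values, one knot per ~25 dense points
# (about 7.5 px of arclength).
ridge_modulation <- function(n, sd) {
  if (sd <= 0) return(rep(0, n))
  n_knot <- max(3L, ceiling(n / 25))
  knots <- seq(1, n, length.out = n_knot)
  m <- stats::splinefun(knots, stats::rnorm(n_knot, 0, sd),
                        method = "natural")(seq_len(n))
  m - mean(m)
}

# Render one fibril (Gaussian transverse profile, apex = local ridge
# height h, scalar or per-point) into matrix M by max-composition over
# its dense centerline points.
render_fibril <- function(M, pts, h, sigma_px) {
  nr <- nrow(M); nc <- ncol(M)
  h <- rep_len(h, nrow(pts))
  R <- ceiling(3 * sigma_px) + 1L
  r0 <- round(pts[, 1]); c0 <- round(pts[, 2])
  for (dr in -R:R) {
    for (dc in -R:R) {
      rr <- r0 + dr; cc <- c0 + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      if (!any(ok)) next
      d2 <- (rr[ok] - pts[ok, 1])^2 + (cc[ok] - pts[ok, 2])^2
      val <- h[ok] * exp(-d2 / (2 * sigma_px^2))
      idx <- (cc[ok] - 1L) * nr + rr[ok]
      o <- order(idx, val)
      idx <- idx[o]; val <- val[o]
      keep <- !duplicated(idx, fromLast = TRUE)
      idx <- idx[keep]; val <- val[keep]
      M[idx] <- pmax(M[idx], val)
    }
  }
  M
}

#' Generate a synthetic AFM topography with ground truth
#'
#' Places the requested fibrils without mutual crossing (centerlines
#' kept at least `min_separation` apart, enforced through a dilated
#' occupancy grid), renders them with Gaussian cross-sections, then adds
#' the tilt plane, per-scanline bow and roughness.
#'
#' @param spec An [afm_sim_spec()].
#' @param max_tries Placement attempts per fibril before giving up.
#' @return A list of class `afm_sim`: `map` (the noisy [height_map()]),
#'   `truth` with `fibrils` (list of `points` (row, col) dense
#'   centerline, `height` (per-fibril mean ridge height, nm),
#'   `height_profile` (local ridge height at each centerline point),
#'   `sigma` nm, `population`), and `clean` (fibril-only surface, no
#'   background or roughness).
#' @export
gen_afm_image <- function(spec, max_tries = 2000L) {
  stopifnot(inherits(spec, "afm_sim_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    px <- spec$pixel_size
    sep_px <- spec$min_separation / px
    r_occ <- if (sep_px > 0) as.integer(ceiling(sep_px) + 2L) else 0L
    occ <- matrix(FALSE, nr, nc)
    clean <- matrix(0, nr, nc)
    margin <- max(4, ceiling(3 * (spec$fibril_width[1] / px)) + 1)
    offsets <- if (r_occ > 0) {
      og <- expand.grid(dr = -r_occ:r_occ, dc = -r_occ:r_occ)
      og[og$dr^2 + og$dc^2 <= r_occ^2, , drop = FALSE]
    } else NULL

    # draw all fibril properties first, then place in shuffled order so
    # field crowding (which shortens late placements) hits every
    # population equally
    draws <- list()
    for (p_i in seq_along(spec$populations)) {
      pop <- spec$populations[[p_i]]
      bf <- min(max(spec$between_fraction, 0), 1)
      sd_between <- sqrt(bf) * pop["sd"]
      sd_along <- sqrt(1 - bf) * pop["sd"]
      for (j in seq_len(pop["count"])) {
        h <- 0
        while (h <= 0.05)
          h <- stats::rnorm(1, pop["mean"], sd_between)
        sigma_nm <- max(stats::rnorm(1, spec$fibril_width[1],
                                     spec$fibril_width[2]), px / 2)
        draws[[length(draws) + 1L]] <-
          list(h = h, sigma = sigma_nm, sd_along = sd_along,
               population = p_i, index = j)
      }
    }
    draws <- draws[sample.int(length(draws))]

    fibrils <- list()
    for (d in draws) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        len_px <- stats::runif(1, spec$fibril_length[1],
                               spec$fibril_length[2]) / px
        pts <- random_centerline(nr, nc, len_px, margin)
        if (is.null(pts)) next
        if (sep_px > 0 &&
            any(occ[cbind(round(pts[, 1]), round(pts[, 2]))])) next
        placed <- TRUE
        break
      }
      if (!placed)
        fm_error(sprintf(
          "could not place fibril %d of population %d (mean %.2f nm) without crossing after %d tries",
          d$index, d$population,
          spec$populations[[d$population]]["mean"], max_tries),
          "fm_placement_error")
      if (!is.null(offsets)) {
        for (k in seq_len(nrow(offsets))) {
          rr <- round(pts[, 1]) + offsets$dr[k]
          cc <- round(pts[, 2]) + offsets$dc[k]
          ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
          occ[cbind(rr[ok], cc[ok])] <- TRUE
        }
      }
      h_along <- pmax(
        d$h + ridge_modulation(nrow(pts), d$sd_along), 0.05)
      clean <- render_fibril(clean, pts, h_along, d$sigma / px)
      fibrils[[length(fibrils) + 1L]] <-
        list(points = pts, height = d$h, height_profile = h_along,
             sigma = d$sigma, population = d$population)
    }

    bg <- spec$background
    tiltmat <- outer((seq_len(nr) - 1) / max(nr - 1, 1) * bg$tilt[1],
                     (seq_len(nc) - 1) / max(nc - 1, 1) * bg$tilt[2], `+`)
    u <- seq(-1, 1, length.out = nc)
    bowmat <- if (bg$bow > 0) {
      a2 <- stats::rnorm(nr, 0, bg$bow)
      a1 <- stats::rnorm(nr, 0, bg$bow / 2)
      outer(a2, u^2) + outer(a1, u)
    } else matrix(0, nr, nc)
    rough <- if (bg$roughness_sd > 0)
      matrix(stats::rnorm(nr * nc, 0, bg$roughness_sd), nr, nc)
    else matrix(0, nr, nc)

    heights <- clean + tiltmat + bowmat + rough
    structure(list(
      map = height_map(heights, px, label = "synthetic"),
      truth = list(fibrils = fibrils, clean = clean)
    ), class = "afm_sim")
  })
}
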