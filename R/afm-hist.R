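# Ridge-height histograms and multi-peak normal-mixture decomposition.

#' Histogram of accepted ridge heights
#'
#' Builds the ridge-height distribution from accepted profile fits
#' (ridge height = fitted Gaussian amplitude). Bin width defaults to
#' 0.25 nm.
#'
#' @param fits List of `profile_fit` objects.
#' @param bin_width Bin width in nm.
#' @return Object of class `height_histogram`: `breaks`, `mids`,
#'   `counts`, `n_profiles` (number of accepted fits).
#' @export
build_histogram <- function(fits, bin_width = 0.25) {
  heights <- vapply(fits, function(f) {
    if (isTRUE(f$accepted)) f$amplitude else NA_real_
  }, numeric(1))
  heights <- heights[!is.na(heights)]
  if (!length(heights))
    fm_error("no accepted profile fits to histogram", "fm_invalid_spec")
  if (length(heights) < 100L)
    fm_warn(sprintf(
      "only %d accepted profiles; histogram decomposition may be unstable",
      length(heights)))
  lo <- floor(min(heights) / bin_width) * bin_width
  hi <- ceiling(max(heights) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- hist(heights, breaks = breaks, plot = FALSE, right = FALSE)
  structure(list(breaks = h$breaks, mids = h$mids, counts = h$counts,
                 n_profiles = length(heights)),
            class = "height_histogram")
}

#' @export
print.height_histogram <- function(x, ...) {
  cat(sprintf("<height_histogram> %d profiles in %d bins over [%.2f, %.2f] nm\n",
              x$n_profiles, length(x$counts), min(x$breaks), max(x$breaks)))
  invisible(x)
}

# Sum of n Gaussian components evaluated at x; p is the packed parameter
# vector (log amplitude, mean, log sd) per component.
mixture_model <- function(x, p) {
  n <- length(p) / 3L
  out <- numeric(length(x))
  for (k in seq_len(n)) {
    A <- exp(p[3 * k - 2]); mu <- p[3 * k - 1]; s <- exp(p[3 * k])
    out <- out + A * exp(-(x - mu)^2 / (2 * s^2))
  }
  out
}

# Candidate mean placements for n components: the visible local maxima
# of the median-smoothed histogram (tallest first, "visible parts of the
# distribution peaks"), count-quantile-spaced means, and equally spaced
# means. Each start is completed with data-driven amplitudes and widths.
init_starts <- function(mids, counts, n) {
  sm <- if (length(counts) >= 5) stats::runmed(counts, 3) else counts
  m <- length(sm)
  is_max <- rep(FALSE, m)
  if (m >= 3)
    is_max[2:(m - 1)] <- sm[2:(m - 1)] >= sm[1:(m - 2)] &
      sm[2:(m - 1)] >= sm[3:m] & sm[2:(m - 1)] > 0
  peaks <- which(is_max)[order(sm[is_max], decreasing = TRUE)]
  cum <- cumsum(counts) / max(sum(counts), 1)
  qmeans <- vapply((seq_len(n) - 0.5) / n,
                   function(q) mids[which.min(abs(cum - q))], numeric(1))
  starts <- list(
    qmeans,
    seq(min(mids), max(mids), length.out = n + 2L)[2:(n + 1L)]
  )
  if (length(peaks)) {
    mus <- mids[peaks]
    if (length(mus) < n)
      mus <- c(mus, qmeans[!qmeans %in% mus])[seq_len(n)]
    starts <- c(list(sort(mus[seq_len(n)])), starts)
  }
  span <- diff(range(mids))
  lapply(starts, function(mus) {
    mus <- sort(mus)
    s0 <- max(span / (4 * n), diff(mids[1:2]))
    as.vector(rbind(
      log(pmax(counts[vapply(mus, function(mu)
        which.min(abs(mids - mu)), integer(1))], 1)),
      mus, log(s0)))
  })
}

fit_mixture_n <- function(mids, counts, n) {
  w <- sqrt(pmax(counts, 1))          # Poisson-motivated weights
  resid <- function(p) (counts - mixture_model(mids, p)) / w
  lower <- rep(c(log(1e-3), min(mids), log(diff(mids[1:2]) / 4)), n)
  upper <- rep(c(log(10 * max(counts) + 10), max(mids),
                 log(diff(range(mids)))), n)
  best <- NULL
  for (p0 in init_starts(mids, counts, n)) {
    opt <- tryCatch(ls_minimize(p0, resid, lower = lower, upper = upper),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$ssr < best$ssr))
      best <- opt
  }
  if (is.null(best))
    fm_error(sprintf("mixture fit failed for n = %d", n), "fm_fit_failure")
  m <- length(counts)
  k <- 3L * n
  rss <- best$ssr
  aicc <- m * log(max(rss, 1e-12) / m) + 2 * k +
    if (m - k - 1 > 0) 2 * k * (k + 1) / (m - k - 1) else Inf
  list(par = best$par, rss = rss, aicc = aicc, n = n)
}

unpack_components <- function(p) {
  n <- length(p) / 3L
  comp <- data.frame(
    amplitude = exp(p[seq(1, 3 * n, by = 3)]),
    mean = p[seq(2, 3 * n, by = 3)],
    sd = exp(p[seq(3, 3 * n, by = 3)])
  )
  comp[order(comp$mean), , drop = FALSE]
}

#' Multi-peak normal-mixture decomposition of a height histogram
#'
#' Fits a sum of normal components (maximal count, mean height, SD per
#' component) to the bin counts by weighted least squares (weights
#' sqrt(count), Poisson-motivated), initialized from the visible
#' histogram maxima. If `n_peaks` is not given, models with 1 to
#' `max_peaks` components are fitted and the small-sample-corrected
#' information criterion (AICc) selects the count. Components whose
#' means fall closer than half the larger SD are merged with a warning.
#'
#' @param hist A [build_histogram()] result with >= 5 occupied bins.
#' @param n_peaks Optional fixed number of components.
#' @param max_peaks Largest model tried during selection (default 6).
#' @return Object of class `peak_mixture_fit`: `peaks` (data frame
#'   amplitude/mean/sd sorted by mean), `n_peaks`, `gof` (R^2 on
#'   counts), `aicc`, `fitted`.
#' @export
fit_multipeak <- function(hist, n_peaks = NULL, max_peaks = 6L) {
  stopifnot(inherits(hist, "height_histogram"))
  if (sum(hist$counts > 0) < 5L)
    fm_error("histogram needs at least 5 occupied bins", "fm_invalid_spec")
  mids <- hist$mids; counts <- hist$counts
  if (is.null(n_peaks)) {
    cand <- lapply(seq_len(max_peaks), function(n)
      tryCatch(fit_mixture_n(mids, counts, n), error = function(e) NULL))
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand))
      fm_error("mixture fit failed for every component count",
               "fm_fit_failure")
    best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "aicc"))]]
  } else {
    best <- fit_mixture_n(mids, counts, n_peaks)
  }
  comp <- unpack_components(best$par)

  # merge components too close to be distinct peaks
  repeat {
    if (nrow(comp) < 2L) break
    gaps <- diff(comp$mean)
    lim <- pmax(comp$sd[-nrow(comp)], comp$sd[-1]) / 2
    bad <- which(gaps < lim)
    if (!length(bad)) break
    fm_warn(sprintf(
      "merging mixture components at %.2f and %.2f nm (means closer than half the larger SD)",
      comp$mean[bad[1]], comp$mean[bad[1] + 1]))
    refit <- fit_mixture_n(mids, counts, nrow(comp) - 1L)
    comp <- unpack_components(refit$par)
    best <- refit
  }

  fitted <- mixture_model(mids, best$par)
  ss_tot <- sum((counts - mean(counts))^2)
  gof <- if (ss_tot > 0) 1 - sum((counts - fitted)^2) / ss_tot else 1
  structure(list(peaks = comp, n_peaks = nrow(comp), gof = gof,
                 aicc = best$aicc, fitted = fitted, mids = mids),
            class = "peak_mixture_fit")
}

#' @export
print.peak_mixture_fit <- function(x, ...) {
  cat(sprintf("<peak_mixture_fit> %d components (R^2 = %.3f)\n",
              x$n_peaks, x$gof))
  for (i in seq_len(nrow(x$peaks)))
    cat(sprintf("  peak %d: mean %.2f nm, sd %.2f nm, max count %.1f\n",
                i, x$peaks$mean[i], x$peaks$sd[i], x$peaks$amplitude[i]))
  invisible(x)
}
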