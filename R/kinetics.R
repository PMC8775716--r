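#' Kinetic trace container
#'
#' A timestamped aggregation signal (ThT fluorescence or mean-residue
#' ellipticity) sampled at strictly increasing times.
#'
#' @param t Sampling times in minutes, strictly increasing, length >= 5.
#' @param y Signal values (arbitrary units or ellipticity), same length as `t`.
#' @param label Free-text label carried through reports.
#' @param normalized Logical flag; set by [normalize_trace()].
#' @param units Optional character vector of length 2 naming the units of
#'   `t` and `y` (recorded by the file readers).
#'
#' @return An object of class `kinetic_trace`.
#' @seealso [normalize_trace()], [fit_boltzmann()]
#' @export
kinetic_trace <- function(t, y, label = "", normalized = FALSE, units = NULL) {
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) != length(y))
    fm_error("t and y must have equal length", "fm_invalid_spec")
  if (length(t) < 5L)
    fm_error("kinetic trace needs at least 5 points", "fm_invalid_spec")
  if (!is_strictly_increasing(t))
    fm_error("t must be strictly increasing", "fm_invalid_spec")
  if (any(!is.finite(t)) || any(!is.finite(y)))
    fm_error("non-finite values in trace", "fm_invalid_spec")
  structure(list(t = t, y = y, label = label, normalized = isTRUE(normalized),
                 units = units),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %s: %d points, t in [%g, %g] min%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$t), min(x$t), max(x$t),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Boltzmann sigmoid for aggregation kinetics
#'
#' Evaluates
#' \deqn{y(t) = y_1 + \frac{y_2 - y_1}{1 + \exp(-2 (t - t_{half}) /
#'   (t_{half} - t_{lag}))}}
#' the standard sigmoidal parameterization of nucleation-growth
#' aggregation curves: `y1`/`y2` are the baseline and plateau signals,
#' `t_half` the time at 50% of maximal signal, and `t_lag` the lag time
#' defined by the tangent construction at the midpoint.
#'
#' @param t Times (minutes).
#' @param y1,y2 Initial and final signal values.
#' @param t_half Aggregation half-time (minutes).
#' @param t_lag Lag time (minutes); must satisfy `t_half > t_lag`.
#' @return Signal values at `t`.
#' @export
boltzmann_curve <- function(t, y1, y2, t_half, t_lag) {
  if (t_half <= t_lag)
    fm_error("t_half must exceed t_lag", "fm_invalid_spec")
  y1 + (y2 - y1) / (1 + exp(-2 * (t - t_half) / (t_half - t_lag)))
}

#' Normalize an aggregation trace
#'
#' `minmax` maps the signal to \[0, 1\] via `(y - min) / (max - min)`
#' (the normalization used for CD ellipticity kinetics,
#' \eqn{\theta_{norm}}); `percent-of-max` maps to `y / max * 100`
#' (maximal mature-fibril signal taken as 100%, as for ThT curves).
#'
#' @param trace A [kinetic_trace()].
#' @param mode `"minmax"` or `"percent-of-max"` (alias `"percent"`).
#' @return A normalized `kinetic_trace` with the `normalized` flag set.
#' @export
normalize_trace <- function(trace, mode = c("minmax", "percent-of-max",
                                            "percent")) {
  stopifnot(inherits(trace, "kinetic_trace"))
  mode <- match.arg(mode)
  if (mode == "percent") mode <- "percent-of-max"
  rng <- range(trace$y)
  if (mode == "minmax") {
    if (diff(rng) == 0)
      fm_error("constant trace cannot be min-max normalized",
               "fm_degenerate_trace")
    y <- (trace$y - rng[1]) / diff(rng)
  } else {
    if (rng[2] == 0)
      fm_error("zero maximum: percent-of-max undefined", "fm_degenerate_trace")
    y <- trace$y / rng[2] * 100
  }
  kinetic_trace(trace$t, y, label = trace$label, normalized = TRUE,
                units = trace$units)
}

#' Apparent aggregation rate constant
#'
#' `k_agg = 2 / (t_half - t_lag)`, the apparent elongation rate constant
#' of the Boltzmann parameterization (1/minutes).
#'
#' @param t_lag Lag time (minutes).
#' @param t_half Half-time (minutes); must exceed `t_lag`.
#' @return Aggregation constant in 1/min.
#' @export
compute_kagg <- function(t_lag, t_half) {
  if (any(t_half <= t_lag))
    fm_error("t_half must exceed t_lag", "fm_domain_error")
  2 / (t_half - t_lag)
}

#' Fit the Boltzmann sigmoid to an aggregation trace
#'
#' Bounded least squares with the geometry `t_half > t_lag >= 0` enforced
#' by fitting `delta = t_half - t_lag` in log space. Starting values are
#' data driven: `y1 = min(y)`, `y2 = max(y)`, `t_half` at the point
#' closest to mid-signal, `t_lag = t_half - range(t)/10`. Parameter
#' standard errors come from the Jacobian at the optimum; `k_agg` is
#' derived from the fitted times and `r` is the Pearson correlation
#' between data and model.
#'
#' @param trace A [kinetic_trace()] with at least 5 points and
#'   non-constant signal.
#' @param max_eval Maximum objective evaluations (default 10000).
#' @return An object of class `boltzmann_fit`: fields `y1`, `y2`,
#'   `t_half`, `t_lag`, `k_agg`, `r`, `se` (named standard errors),
#'   `cov`, `ssr`, `fitted`.
#' @export
fit_boltzmann <- function(trace, max_eval = 10000L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$t; y <- trace$y
  if (diff(range(y)) <= 0)
    fm_error("trace has zero signal range; nothing to fit",
             "fm_degenerate_trace")

  y1_0 <- min(y); y2_0 <- max(y)
  mid <- (y1_0 + y2_0) / 2
  t_half_0 <- t[which.min(abs(y - mid))]
  delta_0 <- diff(range(t)) / 10
  t_lag_0 <- max(t_half_0 - delta_0, 0)
  delta_0 <- max(t_half_0 - t_lag_0, diff(range(t)) / 100)

  # par = (y1, y2, t_lag, log delta); t_half = t_lag + exp(log delta)
  resid <- function(p) {
    y - boltzmann_curve(t, p[1], p[2], p[3] + exp(p[4]), p[3])
  }
  opt <- ls_minimize(c(y1_0, y2_0, t_lag_0, log(delta_0)), resid,
                     lower = c(-Inf, -Inf, 0, -Inf),
                     max_eval = max_eval)
  if (opt$convergence != 0 && !grepl("convergence", opt$message %||% "",
                                     ignore.case = TRUE))
    fm_error(sprintf("Boltzmann fit did not converge: %s", opt$message),
             "fm_fit_failure")

  p <- opt$par
  t_lag <- p[3]; t_half <- p[3] + exp(p[4])
  if (t_half <= t_lag)
    fm_error("fit rejected: t_half <= t_lag", "fm_fit_failure")

  theta <- c(y1 = p[1], y2 = p[2], t_half = t_half, t_lag = t_lag)
  resid_nat <- function(th) y - boltzmann_curve(t, th[1], th[2], th[3], th[4])
  errs <- ls_std_errors(resid_nat, theta)
  fitted <- boltzmann_curve(t, theta[1], theta[2], theta[3], theta[4])

  structure(list(
    y1 = unname(theta[1]), y2 = unname(theta[2]),
    t_half = unname(theta[3]), t_lag = unname(theta[4]),
    k_agg = compute_kagg(t_lag, t_half),
    r = safe_cor(y, fitted),
    se = stats::setNames(errs$se, names(theta)),
    cov = errs$cov, ssr = opt$ssr, fitted = fitted, t = t,
    label = trace$label
  ), class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("<boltzmann_fit>\n")
  cat(sprintf("  y1 = %.4g +/- %.2g   y2 = %.4g +/- %.2g\n",
              x$y1, x$se["y1"], x$y2, x$se["y2"]))
  cat(sprintf("  t_lag  = %.4g +/- %.2g min\n", x$t_lag, x$se["t_lag"]))
  cat(sprintf("  t_half = %.4g +/- %.2g min\n", x$t_half, x$se["t_half"]))
  cat(sprintf("  k_agg  = %.4g 1/min   r = %.5f\n", x$k_agg, x$r))
  invisible(x)
}

#' Correlation between a trace and a fitted model
#'
#' Pearson correlation coefficient between observed signal and model
#' prediction at the same times, the fit-quality statistic reported
#' alongside the kinetic parameters.
#'
#' @param trace A [kinetic_trace()].
#' @param fit A `boltzmann_fit` for that trace.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
fit_quality <- function(trace, fit) {
  stopifnot(inherits(trace, "kinetic_trace"), inherits(fit, "boltzmann_fit"))
  pred <- boltzmann_curve(trace$t, fit$y1, fit$y2, fit$t_half, fit$t_lag)
  safe_cor(trace$y, pred)
}
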