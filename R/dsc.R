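# Two-state DSC analysis: excess heat capacity model with independent
# calorimetric and van't Hoff enthalpies, baseline handling, enthalpy
# integration and reversibility.

# Molar gas constant, kJ/(mol K).
R_GAS <- 8.314462618e-3

#' Thermogram container
#'
#' A DSC scan: excess/apparent heat capacity versus temperature.
#'
#' @param T_c Temperatures in degrees Celsius, strictly increasing,
#'   length >= 20.
#' @param Cp Heat capacity (kJ/mol/degC), same length.
#' @param scan_index 1 for the first heating, 2 for the rescan.
#' @param label Free text.
#' @param baseline_subtracted Logical flag; set by [subtract_baseline()].
#' @return An object of class `thermogram`.
#' @export
thermogram <- function(T_c, Cp, scan_index = 1L, label = "",
                       baseline_subtracted = FALSE) {
  T_c <- as.numeric(T_c); Cp <- as.numeric(Cp)
  if (length(T_c) != length(Cp))
    fm_error("T and Cp must have equal length", "fm_invalid_spec")
  if (length(T_c) < 20L)
    fm_error("thermogram needs at least 20 points", "fm_invalid_spec")
  if (!is_strictly_increasing(T_c))
    fm_error("temperature grid must be strictly increasing", "fm_invalid_spec")
  structure(list(T_c = T_c, Cp = Cp, scan_index = as.integer(scan_index),
                 label = label,
                 baseline_subtracted = isTRUE(baseline_subtracted)),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %s: %d points, T in [%.2f, %.2f] degC, scan %d%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$T_c), min(x$T_c), max(x$T_c), x$scan_index,
              if (x$baseline_subtracted) ", baseline-subtracted" else ""))
  invisible(x)
}

#' Two-state excess heat capacity with independent enthalpies
#'
#' The MicroCal-style "non-two-state" model in which the calorimetric
#' enthalpy (peak area) and the van't Hoff enthalpy (peak sharpness) are
#' independent parameters:
#' \deqn{C_p^{exc}(T) = \frac{\Delta H_{cal} \Delta H_{vH}}{R T^2}
#'   \frac{K}{(1+K)^2}, \quad
#'   K(T) = \exp\left(-\frac{\Delta H_{vH}}{R}
#'   \left(\frac{1}{T} - \frac{1}{T_m}\right)\right)}
#' with temperatures in Kelvin internally and \eqn{T_m} the transition
#' temperature. Its integral over a full bracket equals
#' \eqn{\Delta H_{cal}} exactly, and at \eqn{T = T_d} (where K = 1) it
#' equals \eqn{\Delta H_{cal}\Delta H_{vH} / (4 R T_d^2)}. The unfolding
#' heat-capacity increment is fixed to zero.
#'
#' @param T_c Temperatures (degC).
#' @param T_d Transition temperature (degC).
#' @param dH_cal Calorimetric enthalpy (kJ/mol), positive.
#' @param dH_vH Van't Hoff enthalpy (kJ/mol), positive.
#' @return Excess heat capacity (kJ/mol/degC) at `T_c`.
#' @export
excess_cp_model <- function(T_c, T_d, dH_cal, dH_vH) {
  if (dH_cal <= 0 || dH_vH <= 0)
    fm_error("enthalpies must be positive", "fm_domain_error")
  TK <- T_c + 273.15
  TmK <- T_d + 273.15
  if (TmK <= 0) fm_error("T_d below absolute zero", "fm_domain_error")
  K <- exp(-(dH_vH / R_GAS) * (1 / TK - 1 / TmK))
  dH_cal * dH_vH / (R_GAS * TK^2) * K / (1 + K)^2
}

# Locate flat pre-/post-transition windows. The transition peak and its
# full width at half maximum are estimated on a median-smoothed curve;
# the windows are everything farther than `n_fwhm` half-widths from the
# peak (relaxed stepwise to 2 FWHM if a side would hold fewer than 3
# points). For a two-state peak the excess heat capacity at 3 FWHM is
# below 1e-4 of the peak, so the windows are flat to within noise.
find_flanking_windows <- function(T_c, Cp, n_fwhm = 3) {
  n <- length(T_c)
  k <- max(3L, min(31L, (n %/% 40) * 2 + 1))
  sm <- stats::runmed(Cp, k)
  base0 <- stats::median(sm)
  i_pk <- which.max(abs(sm - base0))
  pk <- sm[i_pk] - base0
  half <- base0 + pk / 2
  above <- if (pk >= 0) sm >= half else sm <= half
  lo <- i_pk; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- i_pk; while (hi < n && above[hi + 1L]) hi <- hi + 1L
  fwhm <- max(T_c[hi] - T_c[lo], diff(range(T_c)) / n)
  for (m in c(n_fwhm, 2.5, 2)) {
    pre <- which(T_c < T_c[i_pk] - m * fwhm)
    post <- which(T_c > T_c[i_pk] + m * fwhm)
    if (length(pre) >= 3L && length(post) >= 3L)
      return(list(pre = pre, post = post, peak = i_pk, fwhm = fwhm))
  }
  fm_error(sprintf(
    "no flat flanking baseline region (peak at %.2f degC, FWHM %.2f degC, grid [%.2f, %.2f])",
    T_c[i_pk], fwhm, min(T_c), max(T_c)), "fm_baseline_failure")
}

#' Subtract the instrumental baseline from a thermogram
#'
#' `linear` subtracts a straight line fitted jointly through the flat
#' pre- and post-transition windows. `progress` (default) subtracts a
#' sigmoid-weighted interpolation between separate pre- and post-
#' transition baseline lines, the weight being the transition progress
#' estimated from the cumulative peak area; this accommodates a step
#' between the folded and unfolded baselines.
#'
#' Flanking windows are auto-detected as the longest runs with smoothed
#' |dCp/dT| below 5% of the peak slope on each side of the transition;
#' pass `windows` (a list with integer index vectors `pre`, `post`) to
#' override.
#'
#' @param tg A [thermogram()].
#' @param method `"progress"` or `"linear"`.
#' @param windows Optional list(pre =, post =) of index vectors.
#' @return A baseline-subtracted `thermogram`.
#' @export
subtract_baseline <- function(tg, method = c("progress", "linear"),
                              windows = NULL) {
  stopifnot(inherits(tg, "thermogram"))
  method <- match.arg(method)
  T_c <- tg$T_c; Cp <- tg$Cp
  if (all(Cp == 0))
    return(thermogram(T_c, Cp, tg$scan_index, tg$label,
                      baseline_subtracted = TRUE))
  w <- windows %||% find_flanking_windows(T_c, Cp)

  line_fit <- function(idx) {
    if (length(idx) < 2L || diff(range(T_c[idx])) == 0) {
      c(mean(Cp[idx]), 0)
    } else {
      unname(stats::lm.fit(cbind(1, T_c[idx]), Cp[idx])$coefficients)
    }
  }
  pre_ln <- line_fit(w$pre)
  post_ln <- line_fit(w$post)

  if (method == "linear") {
    idx <- c(w$pre, w$post)
    co <- stats::lm.fit(cbind(1, T_c[idx]), Cp[idx])$coefficients
    base <- co[1] + co[2] * T_c
  } else {
    pre_b <- pre_ln[1] + pre_ln[2] * T_c
    post_b <- post_ln[1] + post_ln[2] * T_c
    # iterate: progress from the cumulative area of the current
    # baseline-subtracted curve, then re-interpolate
    base <- pre_b
    for (it in 1:3) {
      exc <- pmax(Cp - base, 0)
      area <- cumsum(c(0, (exc[-1] + exc[-length(exc)]) / 2 * diff(T_c)))
      alpha <- if (max(area) > 0) area / max(area) else
        rep(0, length(area))
      base <- (1 - alpha) * pre_b + alpha * post_b
    }
  }
  thermogram(T_c, Cp - base, tg$scan_index, tg$label,
             baseline_subtracted = TRUE)
}

#' Calorimetric enthalpy by integration
#'
#' Trapezoidal integral of a baseline-subtracted excess heat capacity
#' curve over temperature: the calorimetric enthalpy \eqn{\Delta H_{cal}}
#' in kJ/mol.
#'
#' @param tg A baseline-subtracted [thermogram()].
#' @return Enthalpy (kJ/mol).
#' @export
integrate_enthalpy <- function(tg) {
  stopifnot(inherits(tg, "thermogram"))
  trapz(tg$T_c, tg$Cp)
}

#' Fit the two-state model to a thermogram
#'
#' Least-squares fit of [excess_cp_model()] for \eqn{T_d},
#' \eqn{\Delta H_{cal}} and \eqn{\Delta H_{vH}} on a baseline-subtracted
#' scan bracketing a single transition. The cooperativity ratio
#' \eqn{\Delta H_{vH}/\Delta H_{cal}} is attached; a ratio near 1
#' indicates a two-state cooperative unit, above 1 an enlarged
#' cooperative unit (intermolecular cooperation).
#'
#' @param tg A baseline-subtracted [thermogram()].
#' @param max_eval Maximum objective evaluations.
#' @return Object of class `two_state_fit` with fields `T_d` (degC),
#'   `dH_cal`, `dH_vH` (kJ/mol), `ratio`, `se`, `r`, `fitted`,
#'   `reversibility` (NA until [reversibility()] is used).
#' @export
fit_two_state <- function(tg, max_eval = 10000L) {
  stopifnot(inherits(tg, "thermogram"))
  T_c <- tg$T_c; Cp <- tg$Cp
  i_pk <- which.max(Cp)
  if (i_pk <= 2L || i_pk >= length(T_c) - 1L)
    fm_error("peak not bracketed by the temperature grid", "fm_fit_failure")
  Td0 <- T_c[i_pk]
  dHcal0 <- max(trapz(T_c, pmax(Cp, 0)), 1e-3)
  dHvH0 <- max(4 * R_GAS * (Td0 + 273.15)^2 * max(Cp) / dHcal0, 1e-3)

  # par = (T_d degC, log dH_cal, log dH_vH)
  resid <- function(p) Cp - excess_cp_model(T_c, p[1], exp(p[2]), exp(p[3]))
  opt <- ls_minimize(c(Td0, log(dHcal0), log(dHvH0)), resid,
                     max_eval = max_eval)
  if (opt$convergence != 0 && !grepl("convergence", opt$message %||% "",
                                     ignore.case = TRUE))
    fm_error(sprintf("two-state fit did not converge: %s", opt$message),
             "fm_fit_failure")
  theta <- c(T_d = opt$par[1], dH_cal = exp(opt$par[2]),
             dH_vH = exp(opt$par[3]))
  fitted <- excess_cp_model(T_c, theta[1], theta[2], theta[3])
  r <- safe_cor(Cp, fitted)
  if (r^2 < 0.9)
    fm_error(sprintf(
      "residual structure inconsistent with a single two-state transition (R^2 = %.3f)",
      r^2), "fm_fit_failure")
  resid_nat <- function(th) Cp - excess_cp_model(T_c, th[1], th[2], th[3])
  errs <- ls_std_errors(resid_nat, theta)

  structure(list(
    T_d = unname(theta[1]), dH_cal = unname(theta[2]),
    dH_vH = unname(theta[3]),
    ratio = unname(enthalpy_ratio(theta[2], theta[3])),
    reversibility = NA_real_,
    se = stats::setNames(errs$se, names(theta)),
    cov = errs$cov, ssr = opt$ssr, r = r,
    fitted = fitted, T_c = T_c, label = tg$label
  ), class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("<two_state_fit>\n")
  cat(sprintf("  T_d    = %.2f +/- %.2g degC\n", x$T_d, x$se["T_d"]))
  cat(sprintf("  dH_cal = %.1f +/- %.2g kJ/mol\n", x$dH_cal, x$se["dH_cal"]))
  cat(sprintf("  dH_vH  = %.1f +/- %.2g kJ/mol\n", x$dH_vH, x$se["dH_vH"]))
  cat(sprintf("  dH_vH/dH_cal = %.2f", x$ratio))
  if (is.finite(x$reversibility))
    cat(sprintf("   reversibility = %.0f%%", x$reversibility))
  cat("\n")
  invisible(x)
}

#' Cooperativity (enthalpy) ratio
#'
#' Ratio of van't Hoff to calorimetric enthalpy,
#' \eqn{\Delta H_{vH} / \Delta H_{cal}}: ~1 for a two-state monomeric
#' cooperative unit, > 1 when the cooperative unit exceeds the monomer.
#'
#' @param dH_cal Calorimetric enthalpy (kJ/mol), positive.
#' @param dH_vH Van't Hoff enthalpy (kJ/mol), positive.
#' @return Dimensionless ratio.
#' @export
enthalpy_ratio <- function(dH_cal, dH_vH) {
  if (any(dH_cal <= 0) || any(dH_vH <= 0))
    fm_error("enthalpies must be positive", "fm_domain_error")
  dH_vH / dH_cal
}

#' Scan-to-scan reversibility
#'
#' Percentage of the first-scan calorimetric enthalpy recovered in the
#' second heating: `100 * dH_cal(second) / dH_cal(first)`.
#'
#' @param first,second Baseline-subtracted [thermogram()]s of the same
#'   analyte (first heating and immediate rescan).
#' @return Reversibility in percent.
#' @export
reversibility <- function(first, second) {
  stopifnot(inherits(first, "thermogram"), inherits(second, "thermogram"))
  h1 <- integrate_enthalpy(first)
  if (h1 <= 0)
    fm_error("first-scan enthalpy must be positive", "fm_domain_error")
  100 * integrate_enthalpy(second) / h1
}
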