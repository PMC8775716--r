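# Synthetic-data generators for kinetics and DSC pipelines. Every
# stochastic draw derives from the single integer seed in the spec, and
# ground-truth parameters are attached to the generated objects.

#' Simulation spec for an aggregation kinetics trace
#'
#' @param y1,y2 Baseline and plateau signal (arbitrary units).
#' @param t_lag Lag time (minutes), >= 0 and < `t_half`.
#' @param t_half Half-time (minutes).
#' @param t_grid Sampling times (minutes), strictly increasing.
#' @param noise_sd Additive Gaussian noise SD (same units as signal).
#' @param seed Integer seed; all randomness derives from it.
#' @return Object of class `kinetic_sim_spec`.
#' @export
kinetic_sim_spec <- function(y1 = 0, y2 = 100, t_lag = 64.8, t_half = 80.3,
                             t_grid = seq(0, 200, by = 1), noise_sd = 0,
                             seed = 1L) {
  if (t_lag < 0) fm_error("t_lag must be >= 0", "fm_invalid_spec")
  if (t_half <= t_lag)
    fm_error("t_half must exceed t_lag", "fm_invalid_spec")
  if (!is_strictly_increasing(t_grid))
    fm_error("t_grid must be strictly increasing", "fm_invalid_spec")
  if (noise_sd < 0) fm_error("noise_sd must be >= 0", "fm_invalid_spec")
  structure(list(y1 = y1, y2 = y2, t_lag = t_lag, t_half = t_half,
                 t_grid = t_grid, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "kinetic_sim_spec")
}

#' Generate a noisy sigmoidal aggregation trace
#'
#' Evaluates the Boltzmann sigmoid on the spec grid and adds
#' N(0, noise_sd^2) noise. The generating parameters are attached as
#' attribute `truth` for recovery tests.
#'
#' @param spec A [kinetic_sim_spec()].
#' @return A [kinetic_trace()] with attribute `truth`.
#' @export
gen_kinetic_trace <- function(spec) {
  stopifnot(inherits(spec, "kinetic_sim_spec"))
  y <- boltzmann_curve(spec$t_grid, spec$y1, spec$y2, spec$t_half, spec$t_lag)
  if (spec$noise_sd > 0)
    y <- y + with_seed(spec$seed, stats::rnorm(length(y), 0, spec$noise_sd))
  tr <- kinetic_trace(spec$t_grid, y, label = "synthetic")
  attr(tr, "truth") <- spec[c("y1", "y2", "t_lag", "t_half")]
  tr
}

#' Simulation spec for a DSC thermogram
#'
#' The grid must bracket the transition temperature by at least 15 degC
#' on each side so that the excess-heat-capacity peak area is fully
#' contained.
#'
#' @param T_d Transition temperature (degC).
#' @param dH_cal Calorimetric enthalpy (kJ/mol), positive.
#' @param dH_vH Van't Hoff enthalpy (kJ/mol), positive.
#' @param T_grid Temperatures (degC), strictly increasing.
#' @param baseline_coeffs Polynomial baseline coefficients, lowest order
#'   first (kJ/mol/degC per power of degC).
#' @param noise_sd Gaussian Cp noise SD (kJ/mol/degC).
#' @param seed Integer seed.
#' @return Object of class `thermogram_sim_spec`.
#' @export
thermogram_sim_spec <- function(T_d = 66.57, dH_cal = 432.2, dH_vH = 448.5,
                                T_grid = seq(25, 110, by = 0.05),
                                baseline_coeffs = 0, noise_sd = 0,
                                seed = 1L) {
  if (dH_cal <= 0 || dH_vH <= 0)
    fm_error("enthalpies must be positive", "fm_invalid_spec")
  if (!is_strictly_increasing(T_grid))
    fm_error("T_grid must be strictly increasing", "fm_invalid_spec")
  if (min(T_grid) > T_d - 15 || max(T_grid) < T_d + 15)
    fm_error("T_grid must bracket T_d by >= 15 degC on each side",
             "fm_invalid_spec")
  if (noise_sd < 0) fm_error("noise_sd must be >= 0", "fm_invalid_spec")
  structure(list(T_d = T_d, dH_cal = dH_cal, dH_vH = dH_vH, T_grid = T_grid,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "thermogram_sim_spec")
}

#' Generate a two-state DSC thermogram
#'
#' Cp(T) = polynomial baseline + [excess_cp_model()] + Gaussian noise.
#' Generating parameters attached as attribute `truth`.
#'
#' @param spec A [thermogram_sim_spec()].
#' @return A [thermogram()] with attribute `truth`.
#' @export
gen_thermogram <- function(spec) {
  stopifnot(inherits(spec, "thermogram_sim_spec"))
  T_c <- spec$T_grid
  base <- rep(0, length(T_c))
  for (k in seq_along(spec$baseline_coeffs))
    base <- base + spec$baseline_coeffs[k] * T_c^(k - 1)
  Cp <- base + excess_cp_model(T_c, spec$T_d, spec$dH_cal, spec$dH_vH)
  if (spec$noise_sd > 0)
    Cp <- Cp + with_seed(spec$seed, stats::rnorm(length(Cp), 0, spec$noise_sd))
  tg <- thermogram(T_c, Cp, label = "synthetic",
                   baseline_subtracted = all(spec$baseline_coeffs == 0) &&
                     spec$noise_sd == 0)
  attr(tg, "truth") <- spec[c("T_d", "dH_cal", "dH_vH")]
  tg
}
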