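# Run configuration and pipeline orchestration: one structured config,
# all randomness derived from its single seed, a manifest recording
# inputs (with digests), outputs and warnings.

default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "fibrilmorph-run",
    verbosity = 1L,
    inputs = list(trace = NA_character_, dsc_scan = NA_character_,
                  dsc_rescan = NA_character_, afm_map = NA_character_),
    synthetic = list(
      enabled = TRUE,
      kinetics = list(y1 = 0, y2 = 100, t_lag = 64.8, t_half = 80.3,
                      t_max = 200, t_step = 1, noise_sd = 2),
      dsc = list(T_d = 66.57, dH_cal = 432.2, dH_vH = 448.5,
                 T_min = 25, T_max = 110, T_step = 0.05,
                 baseline_coeffs = c(2, 0.01), noise_sd = 0.2,
                 rescan_fraction = 0.98),
      afm = list(rows = 512L, cols = 512L, pixel_size = 4,
                 populations = list(c(2.6, 0.4, 60), c(3.7, 0.8, 60),
                                    c(6.1, 1.1, 60)),
                 roughness_sd = 0.15, min_separation = 16)
    ),
    kinetics = list(normalize = "none"),
    dsc = list(baseline = "progress"),
    afm = list(bin_width = 0.25, half_width = 20, n_peaks = NA_integer_,
               rule = "sqrt_n", flatten_order = 2L)
  )
}

check_keys <- function(user, defaults, path = "") {
  if (!is.list(user)) return(invisible())
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    fm_error(sprintf("unknown config key%s: %s",
                     if (length(unknown) > 1) "s" else "",
                     paste0(path, unknown, collapse = ", ")),
             "fm_config_error")
  for (nm in names(user))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      check_keys(user[[nm]], defaults[[nm]], paste0(path, nm, "."))
  invisible()
}

#' Build a validated run configuration
#'
#' Starts from the documented defaults and overrides them with the
#' entries of `...` (or a nested list passed as `config`). Unknown keys
#' are rejected before any stage runs. Every stochastic stage derives
#' its stream from the single `seed`.
#'
#' @param config Optional nested list of overrides (e.g. parsed from a
#'   JSON config file).
#' @param ... Top-level overrides, e.g. `seed = 7`,
#'   `afm = list(bin_width = 0.5)`.
#' @return Object of class `run_config`.
#' @export
merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    d <- defaults[[nm]]; u <- user[[nm]]
    defaults[[nm]] <-
      if (is.list(d) && is.list(u) && !is.null(names(d)) &&
          all(nzchar(names(d))))
        merge_config(d, u)
      else u   # unnamed lists (e.g. populations) replaced wholesale
  }
  defaults
}

run_config <- function(config = list(), ...) {
  user <- merge_config(config, list(...))
  defaults <- default_run_config()
  check_keys(user, defaults)
  structure(merge_config(defaults, user), class = c("run_config", "list"))
}

log_msg <- function(config, ...) {
  if ((config$verbosity %||% 1L) > 0L)
    message(sprintf(...))
}

#' Run the full synthetic-or-file analysis pipeline
#'
#' Generates synthetic inputs when `config$synthetic$enabled` (otherwise
#' reads the files named in `config$inputs`), runs the three analysis
#' stages (Boltzmann kinetics fit, DSC two-state analysis with
#' reversibility, AFM morphometry), writes all outputs under
#' `config$outdir` and returns (and writes) a manifest listing input
#' digests, the config snapshot, per-stage outputs and warnings. Stage
#' failures abort with the stage name; a partial manifest is still
#' written.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly. Also written as
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  manifest <- list(
    package = "fibrilmorph",
    version = as.character(utils::packageVersion("fibrilmorph")),
    config = unclass(config),
    inputs = list(), outputs = list(), warnings = character(0),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  out_path <- function(name) file.path(config$outdir, name)
  capture_warnings <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        manifest$warnings <<- warnings_log
        jsonlite::write_json(manifest, out_path("manifest.json"),
                             auto_unbox = TRUE, digits = NA, null = "null",
                             force = TRUE)
        fm_error(sprintf("stage '%s' failed: %s", stage,
                         conditionMessage(e)), "fm_stage_error")
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  add_input <- function(name, path) {
    manifest$inputs[[name]] <<- list(path = path,
                                     md5 = unname(tools::md5sum(path)))
  }
  add_output <- function(name, path) {
    manifest$outputs[[name]] <<- path
  }

  # --- synthesize or locate inputs -----------------------------------
  syn <- config$synthetic
  if (isTRUE(syn$enabled)) {
    capture_warnings("synth", {
      ks <- syn$kinetics
      trace <- gen_kinetic_trace(kinetic_sim_spec(
        y1 = ks$y1, y2 = ks$y2, t_lag = ks$t_lag, t_half = ks$t_half,
        t_grid = seq(0, ks$t_max, by = ks$t_step),
        noise_sd = ks$noise_sd, seed = config$seed))
      write_series(trace, out_path("trace.csv"))
      ds <- syn$dsc
      grid <- seq(ds$T_min, ds$T_max, by = ds$T_step)
      tg1 <- gen_thermogram(thermogram_sim_spec(
        T_d = ds$T_d, dH_cal = ds$dH_cal, dH_vH = ds$dH_vH,
        T_grid = grid, baseline_coeffs = ds$baseline_coeffs,
        noise_sd = ds$noise_sd, seed = config$seed + 1L))
      tg2 <- gen_thermogram(thermogram_sim_spec(
        T_d = ds$T_d, dH_cal = ds$dH_cal * ds$rescan_fraction,
        dH_vH = ds$dH_vH, T_grid = grid,
        baseline_coeffs = ds$baseline_coeffs,
        noise_sd = ds$noise_sd, seed = config$seed + 2L))
      write_series(tg1, out_path("dsc_scan1.csv"))
      write_series(tg2, out_path("dsc_scan2.csv"))
      af <- syn$afm
      sim <- gen_afm_image(afm_sim_spec(
        image_shape = c(af$rows, af$cols), pixel_size = af$pixel_size,
        populations = af$populations,
        background = list(tilt = c(12, 8), bow = 2,
                          roughness_sd = af$roughness_sd),
        min_separation = af$min_separation, seed = config$seed + 3L))
      write_heightmap(sim$map, out_path("afm_map.txt"))
      jsonlite::write_json(
        list(heights = vapply(sim$truth$fibrils, `[[`, numeric(1),
                              "height"),
             populations = vapply(sim$truth$fibrils, `[[`, numeric(1),
                                  "population")),
        out_path("afm_truth.json"), digits = NA)
      config$inputs$trace <- out_path("trace.csv")
      config$inputs$dsc_scan <- out_path("dsc_scan1.csv")
      config$inputs$dsc_rescan <- out_path("dsc_scan2.csv")
      config$inputs$afm_map <- out_path("afm_map.txt")
    })
  }

  # --- kinetics -------------------------------------------------------
  if (!is.na(config$inputs$trace)) {
    capture_warnings("kinetics", {
      add_input("trace", config$inputs$trace)
      trace <- read_trace(config$inputs$trace)
      if (config$kinetics$normalize != "none")
        trace <- normalize_trace(trace, config$kinetics$normalize)
      fit <- fit_boltzmann(trace)
      jsonlite::write_json(
        list(y1 = fit$y1, y2 = fit$y2, t_lag = fit$t_lag,
             t_half = fit$t_half, k_agg = fit$k_agg, r = fit$r,
             se = as.list(fit$se)),
        out_path("kinetics_fit.json"), auto_unbox = TRUE, digits = NA)
      utils::write.csv(
        data.frame(t = fit$t, fitted = fit$fitted),
        out_path("kinetics_fitted.csv"), row.names = FALSE)
      add_output("kinetics_fit", out_path("kinetics_fit.json"))
      add_output("kinetics_fitted", out_path("kinetics_fitted.csv"))
      log_msg(config, "kinetics: k_agg = %.4g 1/min (r = %.4f)",
              fit$k_agg, fit$r)
    })
  }

  # --- DSC ------------------------------------------------------------
  if (!is.na(config$inputs$dsc_scan)) {
    capture_warnings("dsc", {
      add_input("dsc_scan", config$inputs$dsc_scan)
      tg1 <- subtract_baseline(read_thermogram(config$inputs$dsc_scan),
                               method = config$dsc$baseline)
      fit <- fit_two_state(tg1)
      if (!is.na(config$inputs$dsc_rescan)) {
        add_input("dsc_rescan", config$inputs$dsc_rescan)
        tg2 <- subtract_baseline(
          read_thermogram(config$inputs$dsc_rescan, scan_index = 2L),
          method = config$dsc$baseline)
        fit$reversibility <- reversibility(tg1, tg2)
      }
      jsonlite::write_json(
        list(T_d = fit$T_d, dH_cal = fit$dH_cal, dH_vH = fit$dH_vH,
             ratio = fit$ratio, reversibility = fit$reversibility,
             dH_cal_integrated = integrate_enthalpy(tg1),
             se = as.list(fit$se)),
        out_path("dsc_fit.json"), auto_unbox = TRUE, digits = NA)
      write_series(tg1, out_path("dsc_baseline_subtracted.csv"))
      add_output("dsc_fit", out_path("dsc_fit.json"))
      add_output("dsc_baseline_subtracted",
                 out_path("dsc_baseline_subtracted.csv"))
      log_msg(config, "dsc: T_d = %.2f degC, ratio = %.2f", fit$T_d,
              fit$ratio)
    })
  }

  # --- AFM ------------------------------------------------------------
  if (!is.na(config$inputs$afm_map)) {
    capture_warnings("afm", {
      add_input("afm_map", config$inputs$afm_map)
      map <- read_heightmap(config$inputs$afm_map)
      np <- config$afm$n_peaks
      ana <- analyze_heightmap(
        map, flatten_order = config$afm$flatten_order,
        half_width = config$afm$half_width,
        bin_width = config$afm$bin_width,
        n_peaks = if (is.na(np)) NULL else np,
        rule = config$afm$rule)
      jsonlite::write_json(
        list(n_paths = length(ana$paths), n_profiles = ana$n_profiles,
             n_accepted = ana$n_accepted,
             median_r = stats::median(ana$accepted_r),
             histogram = list(breaks = ana$histogram$breaks,
                              counts = ana$histogram$counts),
             peaks = ana$mixture$peaks,
             assignments = ana$assignments),
        out_path("afm_analysis.json"), auto_unbox = TRUE, digits = NA,
        null = "null")
      fits_df <- do.call(rbind, lapply(ana$profile_fits, function(f)
        data.frame(position = f$position, width = f$width,
                   amplitude = f$amplitude, baseline = f$baseline,
                   r = f$r, accepted = f$accepted)))
      utils::write.csv(fits_df, out_path("afm_profile_fits.csv"),
                       row.names = FALSE)
      add_output("afm_analysis", out_path("afm_analysis.json"))
      add_output("afm_profile_fits", out_path("afm_profile_fits.csv"))
      log_msg(config, "afm: %d peaks at %s nm", ana$mixture$n_peaks,
              paste(sprintf("%.2f", ana$mixture$peaks$mean),
                    collapse = ", "))
    })
  }

  manifest$warnings <- warnings_log
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
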