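# End-to-end AFM morphometry: flatten -> trace -> normals -> profiles ->
# Gaussian fits -> histogram -> multi-peak fit -> assembly assignment.

#' Analyze an AFM topography end to end
#'
#' Runs the full fibril-morphometry chain on a height map and returns
#' every intermediate product. Ridge heights are the amplitudes of
#' accepted 4-parameter Gaussian cross-section fits; the height
#' histogram is decomposed into normal components and, when
#' `candidate_compositions` is given, peaks are labelled under the
#' hierarchical assembly model with `h1` calibrated from the lowest
#' resolved peak (unless supplied).
#'
#' @param map A [height_map()] (raw; flattening is applied first unless
#'   `map$flattened` is already set).
#' @param flatten_order Scanline polynomial order (default 2).
#' @param seeds Optional live-wire seed pairs (see [trace_ridges()]).
#' @param threshold Optional ridge threshold (nm).
#' @param half_width Cross-section half-width in nm (default 20).
#' @param bin_width Histogram bin width in nm (default 0.25).
#' @param n_peaks Optional fixed number of mixture components.
#' @param r_min Profile acceptance threshold (default 0.95).
#' @param rule Assembly packing rule (default "sqrt_n").
#' @param h1 Protofilament height; default NA calibrates from the lowest
#'   fitted peak.
#' @param candidate_compositions Compositions to consider (default the
#'   hierarchy "1" through "8 + 8").
#' @return List of class `afm_analysis`: `map` (flattened), `paths`,
#'   `profile_fits`, `n_profiles`, `n_accepted`, `histogram`, `mixture`,
#'   `assignments` (or NULL), `accepted_r` (correlation coefficients of
#'   accepted fits).
#' @export
analyze_heightmap <- function(map, flatten_order = 2L, seeds = NULL,
                              threshold = NULL, half_width = 20,
                              bin_width = 0.25, n_peaks = NULL,
                              r_min = 0.95,
                              rule = "sqrt_n", h1 = NA_real_,
                              candidate_compositions =
                                c("1", "1 + 1", "2 + 1", "2 + 2", "4 + 1",
                                  "4 + 2", "4 + 4", "8 + 1", "8 + 8")) {
  stopifnot(inherits(map, "height_map"))
  flat <- if (map$flattened) map else flatten_scanlines(map, flatten_order)
  paths <- trace_ridges(flat, seeds = seeds, threshold = threshold)
  fits <- list()
  for (path in paths) {
    if (nrow(path$points) < 5L) next
    normals <- estimate_normals(path)
    profs <- extract_profiles(path, normals, flat, half_width = half_width)
    for (pr in profs)
      fits[[length(fits) + 1L]] <- fit_profile(pr, r_min = r_min)
  }
  accepted <- vapply(fits, function(f) isTRUE(f$accepted), logical(1))
  if (!any(accepted))
    fm_error("no accepted cross-section fits on this map", "fm_fit_failure")
  hg <- build_histogram(fits, bin_width = bin_width)
  mix <- fit_multipeak(hg, n_peaks = n_peaks)
  assignments <- NULL
  if (length(candidate_compositions)) {
    h1_use <- if (is.finite(h1)) h1 else mix$peaks$mean[1]
    assignments <- assign_fibril_types(
      mix, assembly_model(h1_use, rule), candidate_compositions)
  }
  structure(list(
    map = flat, paths = paths, profile_fits = fits,
    n_profiles = length(fits), n_accepted = sum(accepted),
    histogram = hg, mixture = mix, assignments = assignments,
    accepted_r = vapply(fits[accepted], `[[`, numeric(1), "r")
  ), class = "afm_analysis")
}

#' @export
print.afm_analysis <- function(x, ...) {
  cat(sprintf(
    "<afm_analysis> %d paths, %d/%d profiles accepted (median r = %.3f)\n",
    length(x$paths), x$n_accepted, x$n_profiles,
    stats::median(x$accepted_r)))
  print(x$mixture)
  if (!is.null(x$assignments)) {
    cat("  assignments:\n")
    for (i in seq_len(nrow(x$assignments)))
      cat(sprintf("    %.2f nm -> %s\n", x$assignments$peak_mean[i],
                  x$assignments$label[i]))
  }
  invisible(x)
}
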