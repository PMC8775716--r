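# Hierarchical assembly model: protofilaments intertwine into
# protofibrils, protofibrils into mature fibrils. Compositions are
# written "a + b" (numbers of protofilaments per intertwined strand);
# predicted ridge heights follow a configurable packing rule.

#' Hierarchical assembly model
#'
#' @param h1 Base protofilament ridge height in nm (positive), typically
#'   calibrated from the lowest resolved histogram peak.
#' @param rule Packing rule: `"sqrt_n"` (default; a fibril of n total
#'   protofilaments has height `h1 * sqrt(n)`, the close-packed bundle
#'   scaling), `"pythagorean"` (`h(a+b) = sqrt(h(a)^2 + h(b)^2)` with
#'   balanced-tree sub-heights; coincides with sqrt_n for integer
#'   compositions) or `"additive"` (`h(a+b) = h(a) + h(b)`, loose
#'   stacking).
#' @return Object of class `assembly_model`.
#' @export
assembly_model <- function(h1, rule = c("sqrt_n", "pythagorean", "additive")) {
  if (!is.numeric(h1) || length(h1) != 1L || h1 <= 0)
    fm_error("h1 must be a positive scalar height (nm)", "fm_domain_error")
  structure(list(h1 = h1, rule = match.arg(rule)), class = "assembly_model")
}

# "a + b" (possibly "a + b + c") -> integer vector of strand counts.
parse_composition <- function(comp) {
  comp <- gsub("[()]", "", comp)
  parts <- trimws(strsplit(comp, "+", fixed = TRUE)[[1]])
  if (!length(parts) || !all(grepl("^[0-9]+$", parts)))
    fm_error(sprintf("cannot parse composition '%s'", comp),
             "fm_parse_error")
  n <- as.integer(parts)
  if (any(n < 1L))
    fm_error(sprintf("composition '%s' has a non-positive strand", comp),
             "fm_parse_error")
  n
}

# Height of a single strand of k protofilaments under a rule.
strand_height <- function(k, h1, rule) {
  switch(rule,
    sqrt_n = h1 * sqrt(k),
    additive = h1 * k,
    pythagorean = {
      if (k == 1L) h1
      else sqrt(strand_height(ceiling(k / 2), h1, rule)^2 +
                strand_height(floor(k / 2), h1, rule)^2)
    })
}

#' Predicted ridge heights of fibril compositions
#'
#' @param model An [assembly_model()].
#' @param compositions Character vector of compositions ("1", "1 + 1",
#'   "4 + 4", ...).
#' @return Named numeric vector of predicted heights (nm).
#' @export
predict_heights <- function(model, compositions) {
  stopifnot(inherits(model, "assembly_model"))
  vapply(compositions, function(comp) {
    ks <- parse_composition(comp)
    switch(model$rule,
      sqrt_n = model$h1 * sqrt(sum(ks)),
      additive = sum(vapply(ks, strand_height, numeric(1),
                            h1 = model$h1, rule = "additive")),
      pythagorean = sqrt(sum(vapply(ks, strand_height, numeric(1),
                                    h1 = model$h1,
                                    rule = "pythagorean")^2)))
  }, numeric(1))
}

#' Assign fibril types to mixture peaks
#'
#' Labels every histogram peak with the candidate composition whose
#' predicted height is nearest the peak mean; candidates whose predicted
#' heights tie within `tie_tol` of the best report jointly (multi-label
#' peaks). Peaks below half the protofilament height are labelled
#' `"sub-protofilament"` with a warning.
#'
#' @param mix A [fit_multipeak()] result.
#' @param model An [assembly_model()]; pass `h1 = NA` via
#'   `calibrate = TRUE` is not supported -- instead supply
#'   `assembly_model(h1 = mix$peaks$mean[1])` to calibrate from the
#'   lowest resolved peak.
#' @param candidate_compositions Character vector of candidate
#'   compositions.
#' @param tie_tol Height tolerance (nm) within which candidates tie.
#' @return Data frame of class `fibril_assignment`: peak mean, label,
#'   predicted height, absolute deviation.
#' @export
assign_fibril_types <- function(mix, model, candidate_compositions,
                                tie_tol = 0.25) {
  stopifnot(inherits(mix, "peak_mixture_fit"),
            inherits(model, "assembly_model"))
  preds <- predict_heights(model, candidate_compositions)
  rows <- lapply(seq_len(nrow(mix$peaks)), function(i) {
    mu <- mix$peaks$mean[i]
    if (mu < model$h1 / 2) {
      fm_warn(sprintf(
        "peak at %.2f nm is below half the protofilament height", mu))
      return(data.frame(peak_mean = mu, label = "sub-protofilament",
                        predicted = NA_real_, deviation = NA_real_))
    }
    d <- abs(preds - mu)
    best <- min(d)
    tied <- names(preds)[d <= best + tie_tol]
    data.frame(peak_mean = mu, label = paste(tied, collapse = ", "),
               predicted = unname(preds[which.min(d)]),
               deviation = best)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fibril_assignment", "data.frame")
  out
}
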