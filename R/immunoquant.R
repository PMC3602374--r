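#' Fit an immunoblot standard curve
#'
#' Ordinary least-squares line through (load in fmol, band volume).
#' Chemiluminescent band volume is close to linear in molar load only
#' within the range spanned by the standards, so the curve is flagged
#' unusable when the slope is non-positive or R-squared falls below 0.9,
#' and downstream quantitation guards against extrapolation.
#'
#' @param loads Standard loads, fmol; at least 3, with at least 3
#'   distinct values (duplicate loads are replicates and are allowed in
#'   addition).
#' @param signals Band volumes (a.u.), >= 0, one per load.
#' @return A `standard_curve` list: `slope` (a.u. fmol^-1), `intercept`,
#'   `r_squared`, `usable`, plus the calibration points.
#' @export
#' @examples
#' fit_standard_curve(c(1, 2, 4), c(10, 20, 40))
fit_standard_curve <- function(loads, signals) {
  if (length(loads) != length(signals)) {
    stop_data("loads and signals must have equal length")
  }
  if (length(loads) < 3 || length(unique(loads)) < 3) {
    stop_data("need at least 3 distinct standard loads")
  }
  if (any(signals < 0)) stop_data("signals must be >= 0")
  fit <- stats::lm(signals ~ loads)
  slope <- unname(stats::coef(fit)[2])
  # direct R^2: summary.lm warns on the (legitimate) exact-line case
  tss <- sum((signals - mean(signals))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  structure(
    list(
      loads = loads, signals = signals,
      slope = slope, intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      usable = slope > 0 && r2 >= 0.9
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: slope = %.4g a.u. fmol-1, intercept = %.4g, R2 = %.4f (%s)\n",
    x$slope, x$intercept, x$r_squared,
    if (x$usable) "usable" else "UNUSABLE"
  ))
  invisible(x)
}

#' Quantify a sample lane against a standard curve
#'
#' Back-calculates the molar amount in a sample band by inverting the
#' standard curve, then normalises to the micrograms of total protein
#' loaded.  The sample signal must fall within 0.5x to 1.5x of the
#' standards' signal range (interpolation guard); negative
#' back-calculations (possible with a positive fitted intercept) are
#' floored at zero with a warning.
#'
#' @param curve A usable [fit_standard_curve()] result.
#' @param signal Sample band volume (a.u.).
#' @param ug_loaded Micrograms of total protein loaded in the sample
#'   lane (> 0); blots conventionally load 1 or 3 ug.
#' @return Abundance in fmol per ug total protein.
#' @export
quantify_sample <- function(curve, signal, ug_loaded) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$usable) stop_data("standard curve is flagged unusable")
  if (!(ug_loaded > 0)) stop_data("ug_loaded must be > 0")
  lo <- 0.5 * min(curve$signals)
  hi <- 1.5 * max(curve$signals)
  if (signal < lo || signal > hi) {
    stop_data("signal outside calibrated range [", signif(lo, 4), ", ",
              signif(hi, 4), "]")
  }
  fmol <- (signal - curve$intercept) / curve$slope
  if (fmol < 0) {
    warning("back-calculated amount was negative; floored at 0",
            call. = FALSE)
    fmol <- 0
  }
  fmol / ug_loaded
}

#' Quantify the sample lane of a simulated or imported blot sheet
#'
#' Convenience wrapper: fits the standard curve from the `standard`
#' lanes of a blot data frame (as produced by [simulate_blot()] or read
#' from CSV) and quantifies each `sample` lane.
#'
#' @param blot Data frame with columns `role`, `load_fmol`, `ug_loaded`,
#'   `volume`.
#' @return Numeric vector of fmol per ug, one per sample lane.
#' @export
quantify_blot <- function(blot) {
  std <- blot[blot$role == "standard", ]
  smp <- blot[blot$role == "sample", ]
  if (nrow(smp) == 0) stop_data("blot sheet contains no sample lane")
  curve <- fit_standard_curve(std$load_fmol, std$volume)
  vapply(seq_len(nrow(smp)),
         function(i) quantify_sample(curve, smp$volume[i], smp$ug_loaded[i]),
         numeric(1))
}

#' Total-protein assay by inverse prediction
#'
#' Colourimetric protein assays are read against a standard curve of
#' known concentrations; the sample concentration is the inverse
#' prediction from the fitted line.
#'
#' @param standard_concs Standard concentrations, ug uL^-1; at least 3
#'   distinct values.
#' @param standard_A Assay absorbances of the standards.
#' @param sample_A Assay absorbance of the sample.
#' @return Sample concentration, ug uL^-1.
#' @export
#' @examples
#' protein_assay(c(0.5, 1, 2), c(0.1, 0.2, 0.4), 0.3)
protein_assay <- function(standard_concs, standard_A, sample_A) {
  if (length(standard_concs) != length(standard_A)) {
    stop_data("standards and absorbances must have equal length")
  }
  if (length(standard_concs) < 3 || length(unique(standard_concs)) < 3) {
    stop_data("need at least 3 distinct standards")
  }
  fit <- stats::lm(standard_A ~ standard_concs)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop_data("protein assay standard curve has no response")
  (sample_A - unname(stats::coef(fit)[1])) / slope
}
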