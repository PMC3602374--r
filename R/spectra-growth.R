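#' Exponential growth rate from an optical-density time course
#'
#' Regresses ln(A750) on time within a window (default the first 72 h,
#' before nutrient limitation slows growth) and reports the slope as the
#' specific growth rate with its 95% confidence interval from the
#' t-distribution on the slope.
#'
#' @param times_h Sampling times, h.
#' @param a750 Absorbance at 750 nm (scatter proxy for cell density),
#'   > 0.
#' @param window Two-element numeric, the time window \[t_start, t_end\]
#'   in h over which to fit.
#' @return A `growth_fit` list: `mu` (h^-1), `ci95` (low, high),
#'   `window`, `n_points`, `r_squared`.
#' @export
#' @examples
#' d <- simulate_growth_series(0.019, 0.1, 72, seq(0, 120, 12))
#' growth_rate(d$time_h, d$a750)
growth_rate <- function(times_h, a750, window = c(0, 72)) {
  if (length(times_h) != length(a750)) {
    stop_data("times and absorbances must have equal length")
  }
  keep <- times_h >= window[1] & times_h <= window[2]
  t <- times_h[keep]; a <- a750[keep]
  if (length(t) < 3) stop_data("need at least 3 points inside the window")
  if (any(a <= 0)) stop_data("absorbance must be positive for log regression")
  fit <- stats::lm(log(a) ~ t)
  mu <- unname(stats::coef(fit)[2])
  ci <- suppressWarnings(stats::confint(fit, "t", level = 0.95))
  # an exact log-linear series has zero residual variance; the CI is then
  # degenerate at the point estimate
  if (any(!is.finite(ci))) ci <- c(mu, mu)
  lnA <- log(a)
  tss <- sum((lnA - mean(lnA))^2)
  structure(
    list(
      mu = mu, ci95 = c(ci[1], ci[2]), window = window,
      n_points = length(t),
      r_squared = if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Growth rate: mu = %.4g h-1 (95%% CI %.4g - %.4g), %d points in [%g, %g] h\n",
    x$mu, x$ci95[1], x$ci95[2], x$n_points, x$window[1], x$window[2]
  ))
  invisible(x)
}

#' Pigment indices from three absorbance channels
#'
#' A750 tracks optical scatter (cell density) and serves as the baseline
#' under the pigment bands; A680 sits on the chlorophyll red peak and
#' A630 on the phycobilisome band.  The indices are: chlorophyll
#' absorbance `a680 - a750`; chlorophyll per cell
#' `(a680 - a750) / a750`; and phycobilisome-per-chlorophyll
#' `(a630 - a750) / (a680 - a750)`, which is undefined (returned as
#' `NA`) when a680 does not exceed a750.
#'
#' @param a750,a680,a630 Absorbances at 750, 680 and 630 nm; `a750`
#'   must be > 0.  Vectorised.
#' @return A data frame with columns `chl`, `chl_per_cell`,
#'   `pbs_per_chl`.
#' @export
#' @examples
#' chlorophyll_indices(0.2, 0.5, 0.4)
chlorophyll_indices <- function(a750, a680, a630) {
  if (any(a750 <= 0)) stop_data("a750 must be > 0")
  chl <- a680 - a750
  pbs <- ifelse(chl > 0, (a630 - a750) / chl, NA_real_)
  if (any(chl <= 0)) {
    warning("a680 <= a750 for some points; phycobilisome index undefined",
            call. = FALSE)
  }
  data.frame(chl = chl, chl_per_cell = chl / a750, pbs_per_chl = pbs)
}

#' Chlorophyll absorbance peak wavelength
#'
#' Locates the red chlorophyll absorbance maximum within a wavelength
#' window (default 650-700 nm) by 3-point quadratic interpolation
#' through the grid maximum and its two neighbours, returning the
#' parabola's vertex.  A maximum at the window edge is returned as the
#' edge wavelength with a warning.  The blue shift of this peak under
#' iron limitation tracks the accumulation of chlorophyll bound to IsiA.
#'
#' @param wavelengths_nm Wavelength grid, nm, strictly increasing.
#' @param absorbances Absorbances on that grid.
#' @param window Two-element numeric window in nm.
#' @return Peak wavelength, nm.
#' @export
#' @examples
#' wl <- 650:700
#' peak_wavelength(wl, exp(-((wl - 680) / 10)^2))
peak_wavelength <- function(wavelengths_nm, absorbances,
                            window = c(650, 700)) {
  if (length(wavelengths_nm) != length(absorbances)) {
    stop_data("wavelengths and absorbances must have equal length")
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop_data("wavelengths must be strictly increasing")
  }
  keep <- wavelengths_nm >= window[1] & wavelengths_nm <= window[2]
  wl <- wavelengths_nm[keep]; ab <- absorbances[keep]
  if (length(wl) < 3) stop_data("need at least 3 points inside the window")
  i <- which.max(ab)
  if (i == 1 || i == length(wl)) {
    warning("absorbance maximum lies at the window edge", call. = FALSE)
    return(wl[i])
  }
  # vertex of the parabola through the maximum and its neighbours
  x <- wl[(i - 1):(i + 1)]; y <- ab[(i - 1):(i + 1)]
  denom <- (y[1] - 2 * y[2] + y[3])
  if (denom == 0) {
    warning("flat neighbourhood around the maximum", call. = FALSE)
    return(x[2])
  }
  h1 <- x[2] - x[1]; h2 <- x[3] - x[2]
  # general (possibly uneven) 3-point quadratic vertex
  a <- (y[3] * h1 - y[2] * (h1 + h2) + y[1] * h2) / (h1 * h2 * (h1 + h2))
  b <- (y[3] * h1^2 - y[1] * h2^2 + y[2] * (h2^2 - h1^2)) /
    (h1 * h2 * (h1 + h2))
  x[2] - b / (2 * a)
}
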