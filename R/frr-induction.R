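#' Closed fraction of PSII after a cumulative photon dose
#'
#' Single-turnover closure model for a flashlet train short enough that
#' closed centres cannot re-open.  Without excitonic connectivity
#' (`p = 0`) closure follows the cumulative one-hit Poisson law
#' `C(D) = 1 - exp(-sigma * D)`.  With connectivity `p > 0` excitation
#' arriving at a closed centre can be re-routed to an open neighbour,
#' which accelerates closure; the closed fraction then solves
#' `dC/dD = sigma * (1 - C) / (1 - p * C)` from `C(0) = C0`, integrated
#' numerically with `n_substeps` fourth-order Runge-Kutta sub-steps per
#' dose increment.
#'
#' @param sigma Functional absorption cross-section, A^2 quanta^-1 (>= 0).
#' @param cumulative_dose Cumulative photon dose(s), photons A^-2 (>= 0).
#'   May be a vector; it is integrated in increasing order.
#' @param p Excitonic connectivity in \[0, 1).
#' @param C0 Closed fraction at zero dose, in \[0, 1).
#' @param n_substeps Runge-Kutta sub-steps per dose increment when `p > 0`.
#' @return Closed fraction(s) in \[0, 1\], same length as
#'   `cumulative_dose`.
#' @export
#' @examples
#' closure_fraction(400, log(2) / 400)        # exactly one half
#' closure_fraction(400, 3.6e-4 * 1:40, p = 0.3)
closure_fraction <- function(sigma, cumulative_dose, p = 0, C0 = 0,
                             n_substeps = 100) {
  if (sigma < 0) stop_data("sigma must be >= 0")
  if (any(cumulative_dose < 0)) stop_data("dose must be >= 0")
  if (p < 0 || p >= 1) stop_data("connectivity p must lie in [0, 1)")
  if (C0 < 0 || C0 >= 1) stop_data("C0 must lie in [0, 1)")
  if (p == 0) {
    return(1 - (1 - C0) * exp(-sigma * cumulative_dose))
  }
  ord <- order(cumulative_dose)
  doses <- cumulative_dose[ord]
  out <- numeric(length(doses))
  dCdD <- function(C) sigma * (1 - C) / (1 - p * C)
  C <- C0
  prev <- 0
  for (i in seq_along(doses)) {
    h <- (doses[i] - prev) / n_substeps
    if (h > 0) {
      for (s in seq_len(n_substeps)) {
        k1 <- dCdD(C)
        k2 <- dCdD(C + h / 2 * k1)
        k3 <- dCdD(C + h / 2 * k2)
        k4 <- dCdD(C + h * k3)
        C <- C + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      C <- min(C, 1)
    }
    out[i] <- C
    prev <- doses[i]
  }
  out[ord] <- out
  out
}

#' Map a closed fraction to a fluorescence level
#'
#' Saturation fluorescence map: with `p = 0`,
#' `F = Fo + (Fm - Fo) * C`; with connectivity the fluorescence rise is
#' sigmoidal in C, `F = Fo + (Fm - Fo) * C * (1 - p) / (1 - p * C)`.
#' Both forms satisfy `F(0) = Fo` and `F(1) = Fm`.
#'
#' @param params An [induction_params()] object (supplies Fo, Fm, p).
#' @param C Closed fraction(s) in \[0, 1\].
#' @return Fluorescence in the same arbitrary units as Fo/Fm.
#' @export
model_fluorescence <- function(params, C) {
  stopifnot(inherits(params, "induction_params"))
  if (any(C < 0 | C > 1)) stop_data("C must lie in [0, 1]")
  p <- params$p
  fv <- params$Fm - params$Fo
  if (p == 0) {
    params$Fo + fv * C
  } else {
    params$Fo + fv * C * (1 - p) / (1 - p * C)
  }
}

# Cumulative doses at each flashlet of a transient's protocol.
transient_doses <- function(transient) {
  flashlet_dose(transient$protocol) * seq_along(transient$values)
}

# Shared engine: bounded Levenberg-Marquardt fit of
# F = base + (top - base) * (1 - exp(-sigma * D)) with a deterministic
# multistart on sigma0 x {0.3, 1, 3}; lowest RSS wins, ties broken by
# the smallest sigma.
fit_rise <- function(D, F, base0, top0) {
  fv0 <- top0 - base0
  # dose at half-rise -> sigma0 through the p = 0 closed form
  half <- base0 + fv0 / 2
  i_half <- which(F >= half)[1]
  d_half <- if (is.na(i_half)) max(D) else D[i_half]
  sigma0 <- log(2) / d_half

  best <- NULL
  for (fac in c(0.3, 1, 3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        F ~ base + (top - base) * (1 - exp(-sigma * D)),
        data = list(F = F, D = D),
        start = list(base = base0, top = top0, sigma = sigma0 * fac),
        lower = c(base = 0, top = 0, sigma = 0),
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ptol = 1e-10, ftol = 1e-10
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    sg <- stats::coef(fit)[["sigma"]]
    if (is.null(best) || rss < best$rss - 1e-12 * (1 + best$rss) ||
        (abs(rss - best$rss) <= 1e-12 * (1 + best$rss) && sg < best$sigma)) {
      best <- list(fit = fit, rss = rss, sigma = sg)
    }
  }
  best
}

#' Fit a dark-acclimated single-turnover induction curve
#'
#' Estimates Fo, Fm and sigma_PSII by bounded nonlinear least squares on
#' the flashlet-train fluorescence rise
#' `F_k = Fo + (Fm - Fo) * (1 - exp(-sigma * D_k))`, where `D_k` is the
#' cumulative photon dose after flashlet k computed from the transient's
#' protocol.  Connectivity is fixed at 0.  Initialisation takes Fo from
#' the first point, Fm from the maximum, and sigma from the dose at
#' half-rise, with a deterministic three-point multistart on sigma.
#'
#' @param transient An [frr_transient()] from dark-acclimated cells with
#'   at least 10 flashlets.
#' @return An `induction_fit` list: `Fo`, `Fm`, `sigma` (A^2 quanta^-1),
#'   `FvFm`, `rss`, `converged`.
#' @export
#' @examples
#' pr <- flashlet_protocol()
#' tr <- simulate_frr_transient(induction_params(1, 3, 381), pr)
#' fit_dark_transient(tr)
fit_dark_transient <- function(transient) {
  stopifnot(inherits(transient, "frr_transient"))
  F <- transient$values
  if (length(F) < 10) stop_data("need at least 10 flashlets to fit")
  D <- transient_doses(transient)

  # guard: a flat, non-monotone record carries no variable fluorescence
  res_scale <- stats::sd(diff(F)) / sqrt(2)
  if (any(diff(F) < 0) && diff(range(F)) < 3 * res_scale) {
    stop_data("insufficient variable fluorescence")
  }

  best <- fit_rise(D, F, base0 = F[1], top0 = max(F))
  if (is.null(best)) {
    return(structure(
      list(Fo = NA_real_, Fm = NA_real_, sigma = NA_real_, FvFm = NA_real_,
           rss = NA_real_, converged = FALSE),
      class = "induction_fit"
    ))
  }
  cf <- stats::coef(best$fit)
  Fo <- cf[["base"]]; Fm <- cf[["top"]]
  structure(
    list(
      Fo = Fo, Fm = Fm, sigma = cf[["sigma"]],
      FvFm = (Fm - Fo) / Fm,
      rss = best$rss,
      converged = best$fit$convInfo$isConv
    ),
    class = "induction_fit"
  )
}

#' @export
print.induction_fit <- function(x, ...) {
  cat(sprintf(
    "Induction fit: Fo = %.4g  Fm = %.4g  sigma_PSII = %.4g A2 quanta-1  Fv/Fm = %.4f%s\n",
    x$Fo, x$Fm, x$sigma, x$FvFm,
    if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"
  ))
  invisible(x)
}

#' Fit a light-acclimated single-turnover induction curve
#'
#' Under actinic light a fraction of PSII centres is already closed, so
#' the flashlet train rises from the steady-state level Fs toward Fm'.
#' Fits `F_k = Fs + (Fm' - Fs) * (1 - exp(-sigma' * D_k))` and derives
#' the photochemical quenching coefficient
#' `qP = (Fm' - Fs) / (Fm' - Fo')` and the effective PSII quantum yield
#' `Phi_PSII = (Fm' - Fs) / Fm'`.  `Fo'` is approximated by the
#' dark-measured Fo, an approximation that can push qP above 1 when
#' quenching depresses Fs below Fo; in that case qP is clipped to
#' \[0, 1\] with a warning.
#'
#' @param transient An [frr_transient()] from illuminated cells.
#' @param Fo_dark Dark-acclimated minimal fluorescence used as the Fo'
#'   proxy, > 0.
#' @return A `light_step_fit` list: `Fs`, `Fm_prime`, `sigma_prime`,
#'   `qP`, `Phi_PSII`, `Fo_dark_used`, `rss`, `converged`.
#' @export
fit_light_transient <- function(transient, Fo_dark) {
  stopifnot(inherits(transient, "frr_transient"))
  if (!(Fo_dark > 0)) stop_data("Fo_dark must be > 0")
  F <- transient$values
  if (length(F) < 10) stop_data("need at least 10 flashlets to fit")
  D <- transient_doses(transient)

  best <- fit_rise(D, F, base0 = F[1], top0 = max(F))
  if (is.null(best)) {
    return(structure(
      list(Fs = NA_real_, Fm_prime = NA_real_, sigma_prime = NA_real_,
           qP = NA_real_, Phi_PSII = NA_real_, Fo_dark_used = Fo_dark,
           rss = NA_real_, converged = FALSE),
      class = "light_step_fit"
    ))
  }
  cf <- stats::coef(best$fit)
  Fs <- cf[["base"]]; Fmp <- cf[["top"]]
  if (Fmp <= Fs) stop_data("no variable fluorescence under actinic light")
  qP <- (Fmp - Fs) / (Fmp - Fo_dark)
  if (Fs < Fo_dark) {
    warning("Fs fell below the dark Fo used as the Fo' proxy; ",
            "qP clipped to [0, 1]", call. = FALSE)
  }
  qP <- min(max(qP, 0), 1)
  structure(
    list(
      Fs = Fs, Fm_prime = Fmp, sigma_prime = cf[["sigma"]],
      qP = qP, Phi_PSII = (Fmp - Fs) / Fmp, Fo_dark_used = Fo_dark,
      rss = best$rss, converged = best$fit$convInfo$isConv
    ),
    class = "light_step_fit"
  )
}

#' @export
print.light_step_fit <- function(x, ...) {
  cat(sprintf(
    "Light-step fit: Fs = %.4g  Fm' = %.4g  sigma' = %.4g A2 quanta-1  qP = %.3f  Phi_PSII = %.3f%s\n",
    x$Fs, x$Fm_prime, x$sigma_prime, x$qP, x$Phi_PSII,
    if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"
  ))
  invisible(x)
}
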