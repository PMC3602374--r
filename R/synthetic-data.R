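#' Simulate a dark-acclimated FRR flashlet transient
#'
#' Forward model of a single-turnover fluorescence induction curve: each
#' flashlet deposits a fixed photon dose, progressively closing PSII
#' centres according to [closure_fraction()], and the fluorescence at
#' flashlet k is the closure model evaluated at the cumulative dose,
#' through [model_fluorescence()].  Optional additive Gaussian detector
#' noise.
#'
#' @param params An [induction_params()] object; `C0` must be < 1.
#' @param protocol A [flashlet_protocol()]; the train must stay under
#'   1000 us (re-opening is not modelled).
#' @param noise_sd Additive Gaussian noise standard deviation (a.u.),
#'   >= 0.
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @return An [frr_transient()] with one value per flashlet.
#' @export
#' @examples
#' tr <- simulate_frr_transient(induction_params(1, 3, 381),
#'                              flashlet_protocol(), noise_sd = 0.01,
#'                              seed = 1)
simulate_frr_transient <- function(params, protocol = flashlet_protocol(),
                                   noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "induction_params"),
            inherits(protocol, "flashlet_protocol"))
  if (noise_sd < 0) stop_data("noise_sd must be >= 0")
  doses <- flashlet_dose(protocol) * seq_len(protocol$n_flashlets)
  C <- closure_fraction(params$sigma, doses, p = params$p, C0 = params$C0)
  F <- model_fluorescence(params, C)
  if (noise_sd > 0) {
    F <- with_seed(seed, F + stats::rnorm(length(F), 0, noise_sd))
    F <- pmax(F, .Machine$double.eps)
  }
  frr_transient(flashlet_times(protocol), F, protocol, acclimation = "dark")
}

#' Simulate a light-step FRR transient
#'
#' Emulates a flashlet train fired at cells under actinic illumination:
#' the rise starts from the steady-state fluorescence Fs fixed by the
#' initial closed fraction `C0`, and saturates toward `Fm_prime`, the
#' maximal fluorescence of the illuminated state.  `Fm_prime` is an
#' independent parameter (defaulting to the dark Fm) so that
#' non-photochemical quenching scenarios can be emulated.  At `C0 = 0`
#' and `Fm_prime = Fm` this reduces exactly to
#' [simulate_frr_transient()].
#'
#' @inheritParams simulate_frr_transient
#' @param Fm_prime Maximal fluorescence of the illuminated state (a.u.);
#'   must exceed Fo.
#' @param actinic Actinic irradiance recorded as the transient's
#'   acclimation state, umol photons m^-2 s^-1.
#' @return An [frr_transient()].
#' @export
simulate_light_step <- function(params, protocol = flashlet_protocol(),
                                Fm_prime = params$Fm, noise_sd = 0,
                                seed = NULL, actinic = 66) {
  stopifnot(inherits(params, "induction_params"),
            inherits(protocol, "flashlet_protocol"))
  if (!(Fm_prime > params$Fo)) stop_data("Fm_prime must exceed Fo")
  if (noise_sd < 0) stop_data("noise_sd must be >= 0")
  doses <- flashlet_dose(protocol) * seq_len(protocol$n_flashlets)
  C <- closure_fraction(params$sigma, doses, p = params$p, C0 = params$C0)
  light_params <- induction_params(params$Fo, Fm_prime, params$sigma,
                                   p = params$p, C0 = params$C0)
  F <- model_fluorescence(light_params, C)
  if (noise_sd > 0) {
    F <- with_seed(seed, F + stats::rnorm(length(F), 0, noise_sd))
    F <- pmax(F, .Machine$double.eps)
  }
  frr_transient(flashlet_times(protocol), F, protocol, acclimation = actinic)
}

#' Simulate an optical-density growth series
#'
#' Exponential growth at specific rate `mu` up to `onset_h`, after which
#' the instantaneous rate decays exponentially with timescale `tau_h`
#' (emulating the slowing of growth as a nutrient is depleted):
#' `ln A(t) = ln A(onset) + mu * tau * (1 - exp(-(t - onset)/tau))` for
#' `t > onset`.  Noise is log-normal (multiplicative), matching the
#' error structure of absorbance measurements.
#'
#' @param mu Specific growth rate, h^-1.
#' @param A0 Absorbance at t = 0 (> 0).
#' @param onset_h Time at which growth starts to slow, h.
#' @param times_h Sampling times, h.
#' @param tau_h Decay timescale of the growth rate after onset, h.
#' @param noise_sd Standard deviation of the log-normal noise on the
#'   natural-log scale.
#' @param seed Integer seed.
#' @return A data frame with columns `time_h` and `a750`.
#' @export
#' @examples
#' simulate_growth_series(0.019, 0.1, 72, seq(0, 120, 24))
simulate_growth_series <- function(mu, A0, onset_h = 72,
                                   times_h = seq(0, 120, by = 24),
                                   tau_h = 48, noise_sd = 0, seed = NULL) {
  if (!(A0 > 0)) stop_data("A0 must be > 0")
  if (noise_sd < 0) stop_data("noise_sd must be >= 0")
  lnA <- ifelse(
    times_h <= onset_h,
    log(A0) + mu * times_h,
    log(A0) + mu * onset_h +
      mu * tau_h * (1 - exp(-(times_h - onset_h) / tau_h))
  )
  if (noise_sd > 0) {
    lnA <- with_seed(seed, lnA + stats::rnorm(length(lnA), 0, noise_sd))
  }
  data.frame(time_h = times_h, a750 = exp(lnA))
}

#' Simulate a quantitative immunoblot
#'
#' Generates band volumes for a standard ladder of known loads (fmol)
#' and for a sample lane loaded with `ug_loaded` micrograms of total
#' protein from a culture whose true subunit abundance is
#' `true_fmol_per_ug`.  Band volume responds linearly to the molar load
#' with slope `response_slope`; noise is multiplicative log-normal with
#' coefficient of variation `noise_cv` (unit mean).
#'
#' @param standard_loads Standard loads in fmol; at least 3, positive,
#'   not all identical.
#' @param true_fmol_per_ug Ground-truth subunit abundance,
#'   fmol per ug total protein.
#' @param ug_loaded Micrograms of total protein in the sample lane.
#' @param response_slope Band volume per fmol (a.u. fmol^-1).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return A data frame with columns `lane`, `role`
#'   (`"standard"`/`"sample"`), `load_fmol` (NA for the sample),
#'   `ug_loaded` (NA for standards) and `volume`.
#' @export
#' @examples
#' simulate_blot(c(5, 25, 125, 625), 662, ug_loaded = 1, seed = 1)
simulate_blot <- function(standard_loads, true_fmol_per_ug, ug_loaded = 1,
                          response_slope = 1, noise_cv = 0, seed = NULL) {
  if (length(standard_loads) < 3) stop_data("need at least 3 standard loads")
  if (any(standard_loads <= 0)) stop_data("standard loads must be positive")
  if (length(unique(standard_loads)) < 2) {
    stop_data("standard loads must not all be identical")
  }
  if (true_fmol_per_ug < 0) stop_data("true_fmol_per_ug must be >= 0")
  if (noise_cv < 0) stop_data("noise_cv must be >= 0")
  loads <- c(standard_loads, true_fmol_per_ug * ug_loaded)
  vols <- response_slope * loads
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    vols <- with_seed(seed, {
      vols * stats::rlnorm(length(vols), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
  }
  n_std <- length(standard_loads)
  data.frame(
    lane = seq_len(n_std + 1),
    role = c(rep("standard", n_std), "sample"),
    load_fmol = c(standard_loads, NA_real_),
    ug_loaded = c(rep(NA_real_, n_std), ug_loaded),
    volume = vols
  )
}

#' Simulate an electron-transport light-response dataset
#'
#' Photosynthesis-irradiance points following the saturating curve
#' `ETR(I) = Pmax * tanh(I / EK)` with additive Gaussian noise.
#'
#' @param Pmax Light-saturated electron transport rate (> 0), in the
#'   units the curve will be reported in (e.g. e- PSII^-1 s^-1).
#' @param EK Light-saturation parameter, umol photons m^-2 s^-1 (> 0).
#' @param irradiances Irradiance levels, umol photons m^-2 s^-1.
#' @param noise_sd Additive Gaussian noise SD on ETR.
#' @param seed Integer seed.
#' @return A data frame with columns `irradiance` and `etr`.
#' @export
#' @examples
#' simulate_pe_dataset(96, 90, c(0, 25, 50, 66, 100, 150, 262, 400))
simulate_pe_dataset <- function(Pmax, EK,
                                irradiances = c(0, 25, 50, 66, 100, 150,
                                                262, 400),
                                noise_sd = 0, seed = NULL) {
  if (!(Pmax > 0) || !(EK > 0)) stop_data("Pmax and EK must be positive")
  if (noise_sd < 0) stop_data("noise_sd must be >= 0")
  etr <- Pmax * tanh(irradiances / EK)
  if (noise_sd > 0) {
    etr <- with_seed(seed, etr + stats::rnorm(length(etr), 0, noise_sd))
  }
  data.frame(irradiance = irradiances, etr = etr)
}
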