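#' Single-turnover flashlet protocol
#'
#' Describes the flashlet train of a fast repetition rate (FRR)
#' fluorescence measurement: a series of microsecond excitation flashlets
#' separated by short dark intervals, short enough in total that a closed
#' PSII centre cannot re-open during the train (re-opening takes on the
#' order of 1000 us).  The default protocol is 40 x 2 us flashlets with
#' 2 us gaps (160 us total), with red-orange (625 nm) excitation at
#' 30,000 umol photons m^-2 s^-1; blue (455 nm) excitation defaults to
#' 100,000 umol photons m^-2 s^-1.
#'
#' @param n_flashlets Number of flashlets in the train (>= 2).
#' @param flash_duration_us Duration of each flashlet, microseconds.
#' @param dark_interval_us Dark gap between flashlets, microseconds.
#' @param wavelength_nm Excitation wavelength; 625 or 455 nm pick the
#'   conventional default intensity.
#' @param flash_intensity Flashlet intensity in umol photons m^-2 s^-1;
#'   defaults depend on `wavelength_nm`.
#' @return An object of class `flashlet_protocol`.
#' @export
#' @examples
#' flashlet_protocol()                      # 625 nm default
#' flashlet_protocol(wavelength_nm = 455)   # blue excitation
flashlet_protocol <- function(n_flashlets = 40,
                              flash_duration_us = 2,
                              dark_interval_us = 2,
                              wavelength_nm = 625,
                              flash_intensity = NULL) {
  if (n_flashlets < 2) stop_data("n_flashlets must be >= 2")
  if (flash_duration_us <= 0 || dark_interval_us <= 0) {
    stop_data("flashlet durations must be positive")
  }
  if (is.null(flash_intensity)) {
    flash_intensity <- switch(as.character(wavelength_nm),
      "625" = 30000,
      "455" = 100000,
      stop_data("no default flash intensity for ", wavelength_nm,
                " nm; supply flash_intensity")
    )
  }
  if (flash_intensity <= 0) stop_data("flash_intensity must be positive")
  total_us <- n_flashlets * (flash_duration_us + dark_interval_us)
  if (total_us >= 1000) {
    stop_data("flashlet train lasts ", total_us, " us; trains must stay ",
              "under 1000 us so closed PSII centres cannot re-open")
  }
  structure(
    list(
      n_flashlets = as.integer(n_flashlets),
      flash_duration_us = flash_duration_us,
      dark_interval_us = dark_interval_us,
      wavelength_nm = wavelength_nm,
      flash_intensity = flash_intensity
    ),
    class = "flashlet_protocol"
  )
}

#' Photon dose delivered by one flashlet
#'
#' @param protocol A [flashlet_protocol()].
#' @return Dose in photons A^-2 per flashlet.
#' @export
flashlet_dose <- function(protocol) {
  stopifnot(inherits(protocol, "flashlet_protocol"))
  photon_flux(protocol$flash_intensity) * protocol$flash_duration_us * 1e-6
}

# Measurement times: end of each flashlet's excitation period.
flashlet_times <- function(protocol) {
  k <- seq_len(protocol$n_flashlets)
  (k - 1) * (protocol$flash_duration_us + protocol$dark_interval_us) +
    protocol$flash_duration_us
}

#' Ground-truth parameters of a fluorescence induction curve
#'
#' @param Fo Minimal fluorescence with all PSII open (a.u.), > 0.
#' @param Fm Maximal fluorescence with all PSII closed (a.u.), > Fo.
#' @param sigma Functional absorption cross-section of PSII,
#'   A^2 quanta^-1, > 0 (0 permitted only with `.relax = TRUE`, for
#'   degenerate no-excitation scenarios).
#' @param p Excitonic connectivity between PSII centres, in \[0, 1).
#' @param C0 Initial closed fraction, in \[0, 1); 0 for dark-acclimated
#'   cells.
#' @param .relax Allow `sigma = 0` (testing aid).
#' @return An object of class `induction_params`.
#' @export
induction_params <- function(Fo, Fm, sigma, p = 0, C0 = 0, .relax = FALSE) {
  if (!(Fo > 0)) stop_data("Fo must be > 0")
  if (!(Fm > Fo)) stop_data("Fm must exceed Fo")
  if (.relax) {
    if (sigma < 0) stop_data("sigma must be >= 0")
  } else if (!(sigma > 0)) {
    stop_data("sigma must be > 0")
  }
  if (p < 0 || p >= 1) stop_data("connectivity p must lie in [0, 1)")
  if (C0 < 0 || C0 >= 1) stop_data("initial closed fraction C0 must lie in [0, 1)")
  structure(
    list(Fo = Fo, Fm = Fm, sigma = sigma, p = p, C0 = C0),
    class = "induction_params"
  )
}

#' Construct a fluorescence transient
#'
#' Container for one flashlet train's fluorescence record together with
#' its protocol and acclimation state.
#'
#' @param times_us Measurement times in microseconds, strictly increasing.
#' @param values Fluorescence values (a.u.), finite and positive.
#' @param protocol The [flashlet_protocol()] used.
#' @param acclimation `"dark"` or the actinic irradiance in
#'   umol photons m^-2 s^-1.
#' @return An object of class `frr_transient`.
#' @export
frr_transient <- function(times_us, values, protocol, acclimation = "dark") {
  if (length(times_us) != length(values)) {
    stop_data("times and values must have equal length")
  }
  if (any(diff(times_us) <= 0)) stop_data("times must be strictly increasing")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop_data("fluorescence values must be finite and positive")
  }
  structure(
    list(
      times_us = as.numeric(times_us),
      values = as.numeric(values),
      protocol = protocol,
      acclimation = acclimation,
      wavelength_nm = protocol$wavelength_nm
    ),
    class = "frr_transient"
  )
}

#' @export
print.frr_transient <- function(x, ...) {
  cat("FRR transient:", length(x$values), "flashlets,",
      x$wavelength_nm, "nm,",
      if (identical(x$acclimation, "dark")) "dark-acclimated"
      else paste0("actinic ", x$acclimation, " umol photons m-2 s-1"),
      "\n")
  cat("  F range:", format(min(x$values), digits = 4), "-",
      format(max(x$values), digits = 4), "a.u.\n")
  invisible(x)
}
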