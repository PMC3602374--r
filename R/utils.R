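# photons A^-2 s^-1 delivered per umol photons m^-2 s^-1:
# 6.02214076e23 photons/mol * 1e-6 mol/umol * 1e-20 m^2/A^2
PHOTON_CONV <- 6.02214076e-3

#' Convert irradiance to photon flux density per square Angstrom
#'
#' Photosynthetic irradiances are conventionally reported in
#' umol photons m^-2 s^-1 while functional absorption cross-sections
#' (sigma_PSII) are reported in A^2 quanta^-1.  Their product only has
#' meaning after converting the irradiance to photons A^-2 s^-1.
#'
#' @param irradiance Irradiance in umol photons m^-2 s^-1.
#' @return Photon flux density in photons A^-2 s^-1.
#' @export
#' @examples
#' photon_flux(30000)          # a 625 nm single-turnover flashlet
photon_flux <- function(irradiance) {
  stopifnot(is.numeric(irradiance), all(irradiance >= 0))
  irradiance * PHOTON_CONV
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.  `seed = NULL` leaves the
# RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Derive a stage-specific child seed from a root seed, staying below 2^31.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stop_data <- function(...) stop(..., call. = FALSE)
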