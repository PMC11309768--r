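#' Physical constants for amide 15N relaxation
#'
#' Bundle of the physical constants entering the dipolar/CSA relaxation
#' equations for a backbone N-H spin pair. Defaults follow common usage in
#' backbone dynamics analysis: an effective N-H bond length of 1.02 A and an
#' axially symmetric 15N chemical-shift anisotropy of -172 ppm.
#'
#' @param rNH N-H bond length in metres.
#' @param dsigmaN 15N chemical shift anisotropy (dimensionless, i.e. ppm/1e6
#'   already applied; pass `-172e-6` for -172 ppm).
#' @param gammaH,gammaN 1H and 15N gyromagnetic ratios, rad s^-1 T^-1.
#' @return An object of class `nmr_constants`.
#' @export
nmr_constants <- function(rNH = 1.02e-10,
                          dsigmaN = -172e-6,
                          gammaH = 2.6752218744e8,
                          gammaN = -2.7126e7) {
  stopifnot(rNH > 0)
  structure(
    list(rNH = rNH, dsigmaN = dsigmaN, gammaH = gammaH, gammaN = gammaN),
    class = "nmr_constants"
  )
}

# reduced Planck constant (J s) and mu0/4pi (T m / A)
.hbar <- 1.054571817e-34
.mu0_4pi <- 1e-7

#' Dipolar coupling constant d (rad/s) for an N-H pair
#' @param constants an [nmr_constants()] object.
#' @return d = (mu0/4pi) * hbar * gammaH * gammaN / rNH^3, rad/s.
#' @keywords internal
dipolar_constant <- function(constants) {
  .mu0_4pi * .hbar * constants$gammaH * constants$gammaN / constants$rNH^3
}

#' CSA constant c (rad/s) at a given 15N Larmor frequency
#' @param omegaN 15N angular frequency, rad/s.
#' @param constants an [nmr_constants()] object.
#' @keywords internal
csa_constant <- function(omegaN, constants) {
  omegaN * constants$dsigmaN / sqrt(3)
}

#' Spectrometer context
#'
#' Field-dependent angular frequencies for 1H and 15N. The 15N frequency is
#' derived from the 1H frequency through the gyromagnetic-ratio quotient, so
#' `omegaN / omegaH == gammaN / gammaH` holds by construction.
#'
#' @param proton_mhz 1H resonance frequency in MHz (e.g. 600 or 800).
#' @param temperature sample temperature, K.
#' @param constants an [nmr_constants()] object supplying the gyromagnetic
#'   ratios.
#' @return An object of class `spectrometer_context` with fields
#'   `proton_mhz`, `omegaH`, `omegaN` (rad/s; `omegaN` is negative because
#'   gammaN < 0), `B0` (T) and `temperature`.
#' @export
spectrometer_context <- function(proton_mhz, temperature = 298,
                                 constants = nmr_constants()) {
  stopifnot(is.numeric(proton_mhz), proton_mhz > 0)
  omegaH <- 2 * pi * proton_mhz * 1e6
  omegaN <- omegaH * constants$gammaN / constants$gammaH
  structure(
    list(proton_mhz = proton_mhz,
         omegaH = omegaH,
         omegaN = omegaN,
         B0 = omegaH / constants$gammaH,
         temperature = temperature),
    class = "spectrometer_context"
  )
}
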