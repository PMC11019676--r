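#' Optical properties of a liquid tissue phantom base
#'
#' A phantom base is an aqueous mixture of a scatterer (intralipid) and an
#' absorber (India ink). Its optical properties are anchored at a reference
#' wavelength and reference volume fractions: with the defaults, 4 % of the
#' 20 % intralipid stock and 0.5 % of the ink stock give a reduced
#' scattering coefficient of 8.3 cm^-1 and an absorption coefficient of
#' 0.32 cm^-1 at 470 nm, values typical of cortical brain tissue.
#'
#' Scattering follows the usual intralipid power law
#' \eqn{\mu_s'(\lambda) = \mu_{s,ref}' (\lambda/\lambda_{ref})^{-b}} and
#' scales linearly with the scatterer volume fraction. Absorption is
#' spectrally flat by default (India ink is nearly grey over 300--700 nm)
#' and scales linearly with the absorber fraction; a different spectral
#' shape can be supplied as a function of wavelength.
#'
#' @param musp_ref Reduced scattering coefficient (cm^-1) at
#'   `ref_wavelength` for `ref_scatterer_fraction`.
#' @param mua_ref Absorption coefficient (cm^-1) at `ref_wavelength` for
#'   `ref_absorber_fraction`.
#' @param ref_wavelength Reference wavelength in nm.
#' @param scatter_power Dimensionless scattering power-law exponent b.
#' @param ref_scatterer_fraction Scatterer volume fraction (%) at which
#'   `musp_ref` holds.
#' @param ref_absorber_fraction Absorber volume fraction (%) at which
#'   `mua_ref` holds.
#' @param absorber_shape Optional function of wavelength (nm) returning the
#'   relative absorber absorption (1 at all wavelengths when `NULL`).
#'
#' @return An object of class `"optical_medium"`.
#' @examples
#' med <- optical_medium()
#' reduced_scattering(med, 470)   # 8.3 cm^-1
#' absorption_coefficient(med, 470)  # 0.32 cm^-1
#' @export
optical_medium <- function(musp_ref = 8.3, mua_ref = 0.32,
                           ref_wavelength = 470, scatter_power = 2.4,
                           ref_scatterer_fraction = 4,
                           ref_absorber_fraction = 0.5,
                           absorber_shape = NULL) {
  stopifnot(mua_ref >= 0, musp_ref > 0, ref_wavelength > 0,
            ref_scatterer_fraction > 0, ref_absorber_fraction > 0)
  if (!is.null(absorber_shape)) stopifnot(is.function(absorber_shape))
  structure(
    list(musp_ref = musp_ref, mua_ref = mua_ref,
         ref_wavelength = ref_wavelength, scatter_power = scatter_power,
         ref_scatterer_fraction = ref_scatterer_fraction,
         ref_absorber_fraction = ref_absorber_fraction,
         absorber_shape = absorber_shape),
    class = "optical_medium"
  )
}

check_wavelength <- function(wavelength) {
  if (any(wavelength < 250 | wavelength > 800)) {
    stop("wavelength must lie in [250, 800] nm", call. = FALSE)
  }
  invisible(wavelength)
}

#' Reduced scattering coefficient at a wavelength
#'
#' @param medium An [optical_medium()].
#' @param wavelength Wavelength(s) in nm, within 250--800.
#' @param scatterer_fraction Scatterer volume fraction (%); defaults to the
#'   medium's reference fraction.
#' @return Reduced scattering coefficient(s) in cm^-1.
#' @export
reduced_scattering <- function(medium, wavelength,
                               scatterer_fraction = medium$ref_scatterer_fraction) {
  check_wavelength(wavelength)
  stopifnot(scatterer_fraction >= 0)
  medium$musp_ref *
    (wavelength / medium$ref_wavelength)^(-medium$scatter_power) *
    (scatterer_fraction / medium$ref_scatterer_fraction)
}

#' Absorption coefficient at a wavelength
#'
#' @inheritParams reduced_scattering
#' @param absorber_fraction Absorber volume fraction (%); defaults to the
#'   medium's reference fraction.
#' @return Absorption coefficient(s) in cm^-1.
#' @export
absorption_coefficient <- function(medium, wavelength,
                                   absorber_fraction = medium$ref_absorber_fraction) {
  check_wavelength(wavelength)
  stopifnot(absorber_fraction >= 0)
  shape <- if (is.null(medium$absorber_shape)) 1 else medium$absorber_shape(wavelength)
  medium$mua_ref * shape * (absorber_fraction / medium$ref_absorber_fraction)
}

#' Effective attenuation coefficient
#'
#' Diffusion-theory closure \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}}
#' used to attenuate both illumination and remitted light over an effective
#' path length.
#'
#' @param mua Absorption coefficient(s), cm^-1, non-negative.
#' @param musp Reduced scattering coefficient(s), cm^-1, positive.
#' @return Effective attenuation coefficient(s) in cm^-1.
#' @export
effective_attenuation <- function(mua, musp) {
  if (any(mua < 0) || any(musp <= 0)) {
    stop("mua must be >= 0 and musp > 0", call. = FALSE)
  }
  sqrt(3 * mua * (mua + musp))
}

# mu_eff for a sample's absorber/scatterer fractions at given wavelengths
mu_eff_at <- function(medium, wavelength, absorber_fraction, scatterer_fraction) {
  mua <- absorption_coefficient(medium, wavelength, absorber_fraction)
  musp <- reduced_scattering(medium, wavelength, scatterer_fraction)
  # a fraction-free medium is non-scattering; attenuation is then absorption-only
  ifelse(musp > 0, sqrt(3 * mua * (mua + musp)), mua)
}
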