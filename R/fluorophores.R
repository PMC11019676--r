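#' Fluorophore panel
#'
#' Returns the default fluorophore table: NADH and FAD (endogenous
#' metabolic cofactors) and protoporphyrin IX (PpIX, the 5-ALA metabolite
#' used for tumour contrast). Excitation and emission spectra are modelled
#' as Gaussian bands parameterised by peak and FWHM; `molar_response` is
#' the emitted power (nW, at the instrument's collection geometry) per
#' unit concentration (ug/ml) under unit source power at the excitation
#' peak, before the quantum-yield factor. `matched_source` and
#' `matched_channel` name the instrument (source, channel) wavelength pair
#' conventionally used to read that fluorophore out.
#'
#' @details The matched pairs follow the instrument convention:
#' NADH (340, 470), FAD (440, 590), PpIX (340, 680). Note the PpIX pair
#' keeps the instrument's 340 nm assignment even though PpIX's Soret band
#' near 405 nm means the 390/440 nm sources excite it more strongly; the
#' specificity diagnostics make this visible.
#'
#' @return A tibble with one row per fluorophore and columns `name`,
#'   `ex_peak`, `ex_fwhm`, `em_peak`, `em_fwhm`, `quantum_yield`,
#'   `molar_response`, `matched_source`, `matched_channel` (wavelengths nm).
#' @examples
#' default_fluorophores()
#' @export
default_fluorophores <- function() {
  fl <- tibble::tribble(
    ~name,   ~ex_peak, ~ex_fwhm, ~em_peak, ~em_fwhm, ~quantum_yield,
    ~molar_response, ~matched_source, ~matched_channel,
    "nadh",  340,      60,       460,      80,       0.02,  300, 340, 470,
    "fad",   450,      60,       525,      80,       0.30,   80, 440, 590,
    "ppix",  405,      60,       635,      80,       0.06,  800, 340, 680
  )
  validate_fluorophores(fl)
}

validate_fluorophores <- function(fluorophores) {
  stopifnot(is.data.frame(fluorophores))
  req <- c("name", "ex_peak", "ex_fwhm", "em_peak", "em_fwhm",
           "quantum_yield", "molar_response")
  missing <- setdiff(req, names(fluorophores))
  if (length(missing)) {
    stop("fluorophore table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(fluorophores$em_peak <= fluorophores$ex_peak)) {
    stop("emission peak must exceed excitation peak (Stokes shift)",
         call. = FALSE)
  }
  if (any(fluorophores$ex_fwhm <= 0) || any(fluorophores$em_fwhm <= 0)) {
    stop("spectral FWHM must be positive", call. = FALSE)
  }
  if (any(fluorophores$quantum_yield <= 0 | fluorophores$quantum_yield > 1)) {
    stop("quantum_yield must lie in (0, 1]", call. = FALSE)
  }
  if (any(fluorophores$molar_response < 0)) {
    stop("molar_response must be non-negative", call. = FALSE)
  }
  tibble::as_tibble(fluorophores)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# relative excitation efficiency at `wavelength` (1 at the excitation peak)
excitation_efficiency <- function(ex_peak, ex_fwhm, wavelength) {
  s <- fwhm_to_sigma(ex_fwhm)
  exp(-((wavelength - ex_peak)^2) / (2 * s^2))
}

# fraction of the (unit-area Gaussian) emission band falling inside a
# detection channel's passband [center - fwhm/2, center + fwhm/2]
emission_fraction <- function(em_peak, em_fwhm, channel_center, channel_fwhm) {
  s <- fwhm_to_sigma(em_fwhm)
  stats::pnorm(channel_center + channel_fwhm / 2, em_peak, s) -
    stats::pnorm(channel_center - channel_fwhm / 2, em_peak, s)
}
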