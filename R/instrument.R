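#' Instrument configuration
#'
#' Describes the multi-spectral fibre-probe instrument: eight illumination
#' sources (300--680 nm; the 300, 340 and 590 nm sources are LEDs with
#' lower coupled power than the laser diodes), eight SiPMT detection
#' channels with bandpass widths matching the dichroic stack, a
#' photodiode for diffuse reflectance (DRS), an illumination-leakage
#' (crosstalk) matrix, the detector's linear range and saturation limit,
#' and noise parameters.
#'
#' @details
#' SiPMT outputs are voltages: incident power (nW) times `gain` (V/nW),
#' hard-clipped at `v_max`. The default gain maps the top of the detector's
#' linear range (37 nW) onto the 5 V saturation ceiling. `reflex_gain`
#' sets how much reflected excitation light (nW per unit source power,
#' before attenuation in the medium) reaches the detection path; leakage
#' of that light into channel `i` under source `j` is `crosstalk[i, j]`,
#' with the matched channel (`i == j`) equal to 1 by convention. With the
#' default powers and `reflex_gain`, reflected excitation saturates the
#' matched channels of the four strong laser sources (440, 470, 515,
#' 680 nm) in every acquisition, reproducing the behaviour of a
#' high-sensitivity fluorescence detector exposed to the much stronger
#' DRS-scale return.
#'
#' Per illumination state, a single lognormal source-fluctuation factor
#' (CV `noise_source_cv`) multiplies the true optical signal on *all*
#' detectors of that state (same flash), additive Gaussian read noise
#' (`noise_detector_sd`, volts) is applied per detector, and a constant
#' ambient background `ambient_level` (volts) is present in every state
#' including the dark state.
#'
#' @param source_wavelengths Strictly increasing source wavelengths (nm).
#' @param source_powers Radiant power per source (arbitrary units).
#' @param channel_centers Strictly increasing detection-channel centers (nm).
#' @param channel_fwhm Passband FWHM of each detection channel (nm).
#' @param crosstalk Leakage-fraction matrix `[channel x source]` in `[0, 1]`
#'   applied to reflected excitation light; see [default_crosstalk()].
#' @param v_max SiPMT saturation ceiling (V).
#' @param linear_range Two-element `(min, max)` linear input range (nW).
#' @param pd_max Photodiode upper limit (mW scale; far from binding here).
#' @param gain SiPMT conversion, V per nW.
#' @param drs_gain Photodiode conversion (arbitrary units per source power).
#' @param reflex_gain Reflected excitation power reaching the fluorescence
#'   detection path, nW per unit source power before medium attenuation.
#' @param noise_source_cv Coefficient of variation of per-flash source
#'   fluctuation (lognormal, mean 1).
#' @param noise_detector_sd Additive detector read noise, volts.
#' @param ambient_level Ambient background level, volts.
#' @param sd_separation_fluor Effective one-way optical path (cm) for the
#'   fluorescence fibre (applied once at excitation, once at emission).
#' @param sd_separation_drs Effective optical path (cm) for the DRS fibre,
#'   offset ~1 mm from the sources.
#'
#' @return An object of class `"instrument_spec"`.
#' @examples
#' inst <- instrument_spec()
#' inst$source_wavelengths
#' @export
instrument_spec <- function(source_wavelengths = c(300, 340, 390, 440, 470, 515, 590, 680),
                            source_powers = c(0.2, 0.5, 0.7, 1, 1, 1, 0.6, 1),
                            channel_centers = source_wavelengths,
                            channel_fwhm = 25,
                            crosstalk = default_crosstalk(channel_centers, source_wavelengths),
                            v_max = 5,
                            linear_range = c(0.03, 37),
                            pd_max = 22,
                            gain = 5 / 37,
                            drs_gain = 1,
                            reflex_gain = 60,
                            noise_source_cv = 0.02,
                            noise_detector_sd = 1e-4,
                            ambient_level = 0.05,
                            sd_separation_fluor = 0.05,
                            sd_separation_drs = 0.1) {
  stopifnot(length(source_wavelengths) == length(source_powers),
            all(diff(source_wavelengths) > 0),
            all(diff(channel_centers) > 0),
            all(source_powers >= 0),
            is.matrix(crosstalk),
            nrow(crosstalk) == length(channel_centers),
            ncol(crosstalk) == length(source_wavelengths),
            all(crosstalk >= 0 & crosstalk <= 1),
            v_max > 0, gain > 0, drs_gain > 0, reflex_gain >= 0,
            length(linear_range) == 2, linear_range[1] < linear_range[2],
            noise_source_cv >= 0, noise_detector_sd >= 0, ambient_level >= 0,
            sd_separation_fluor > 0, sd_separation_drs > 0)
  dimnames(crosstalk) <- list(channel = as.character(channel_centers),
                              source = as.character(source_wavelengths))
  structure(
    list(source_wavelengths = source_wavelengths,
         source_powers = source_powers,
         channel_centers = channel_centers,
         channel_fwhm = channel_fwhm,
         crosstalk = crosstalk,
         v_max = v_max,
         linear_range = linear_range,
         pd_max = pd_max,
         gain = gain,
         drs_gain = drs_gain,
         reflex_gain = reflex_gain,
         noise_source_cv = noise_source_cv,
         noise_detector_sd = noise_detector_sd,
         ambient_level = ambient_level,
         sd_separation_fluor = sd_separation_fluor,
         sd_separation_drs = sd_separation_drs),
    class = "instrument_spec"
  )
}

#' Default illumination-leakage (crosstalk) matrix
#'
#' Leakage fraction of reflected excitation light into each detection
#' channel, `[channel x source]`. The matched channel (center equal to the
#' source wavelength) passes the reflected excitation fully (entry 1).
#' Channels *below* the source wavelength leak strongly (default 5 %):
#' the bandpass coatings lose blocking far out of band, so short-wavelength
#' channels "steal" light — these pairs carry no fluorescence information
#' and are masked out of the feature matrix anyway. Channels above the
#' source leak weakly (default 0.01 %), with three measured pairs pinned
#' to their characterised values: 1e-3 % at (source 340, channel 470),
#' 2.5e-2 % at (440, 590) and 2e-3 % at (340, 680).
#'
#' @param channel_centers Channel center wavelengths (nm).
#' @param source_wavelengths Source wavelengths (nm).
#' @param below Leakage fraction into channels below the source wavelength.
#' @param above Leakage fraction into channels above the source wavelength.
#' @return A `[channel x source]` matrix of leakage fractions.
#' @export
default_crosstalk <- function(channel_centers = c(300, 340, 390, 440, 470, 515, 590, 680),
                              source_wavelengths = channel_centers,
                              below = 0.05, above = 1e-4) {
  ct <- matrix(above, nrow = length(channel_centers),
               ncol = length(source_wavelengths),
               dimnames = list(channel = as.character(channel_centers),
                               source = as.character(source_wavelengths)))
  for (j in seq_along(source_wavelengths)) {
    ct[channel_centers < source_wavelengths[j], j] <- below
    ct[channel_centers == source_wavelengths[j], j] <- 1
  }
  pin <- function(ch, src, val) {
    i <- match(ch, channel_centers); j <- match(src, source_wavelengths)
    if (!is.na(i) && !is.na(j)) ct[i, j] <<- val
  }
  pin(470, 340, 1e-5)   # NADH excitation -> emission channel
  pin(590, 440, 2.5e-4) # FAD pair
  pin(680, 340, 2e-5)   # PpIX pair
  ct
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat("<instrument_spec>\n")
  cat("  sources (nm):  ", paste(x$source_wavelengths, collapse = ", "), "\n")
  cat("  channels (nm): ", paste(x$channel_centers, collapse = ", "),
      " (fwhm ", x$channel_fwhm, " nm)\n", sep = "")
  cat("  v_max: ", x$v_max, " V; linear range: ",
      x$linear_range[1], "-", x$linear_range[2], " nW; gain: ",
      signif(x$gain, 4), " V/nW\n", sep = "")
  cat("  noise: source CV ", x$noise_source_cv, ", detector sd ",
      x$noise_detector_sd, " V, ambient ", x$ambient_level, " V\n", sep = "")
  invisible(x)
}

#' A noise- and background-free copy of an instrument
#'
#' Convenience for forward-model and round-trip checks: zeroes the source
#' fluctuation, detector read noise and ambient background while keeping
#' the optical configuration (including saturation) intact.
#'
#' @param instrument An [instrument_spec()].
#' @param power_scale Optional multiplier on all source powers, e.g. to
#'   keep a characterisation measurement inside the detector's linear
#'   range (the software analogue of inserting a neutral-density filter).
#' @return An `instrument_spec`.
#' @export
quiet_instrument <- function(instrument = instrument_spec(), power_scale = 1) {
  instrument$noise_source_cv <- 0
  instrument$noise_detector_sd <- 0
  instrument$ambient_level <- 0
  instrument$source_powers <- instrument$source_powers * power_scale
  instrument
}
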