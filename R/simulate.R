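#' @keywords internal
sample_conc <- function(sample, fluorophores) {
  vapply(fluorophores$name, function(nm) {
    v <- if (nm %in% names(sample)) sample[[nm]][1] else 0
    if (is.na(v)) 0 else v
  }, numeric(1))
}

require_source <- function(instrument, source_wavelength) {
  if (!source_wavelength %in% instrument$source_wavelengths) {
    stop("unknown source wavelength: ", source_wavelength, call. = FALSE)
  }
  match(source_wavelength, instrument$source_wavelengths)
}

require_channel <- function(instrument, channel_center) {
  if (!channel_center %in% instrument$channel_centers) {
    stop("unknown channel center: ", channel_center, call. = FALSE)
  }
  match(channel_center, instrument$channel_centers)
}

#' Noiseless diffuse reflectance at the photodiode
#'
#' Modified Beer--Lambert closure: source power times the photodiode gain,
#' attenuated by `exp(-mu_eff(lambda) * rho_drs)` where `rho_drs` is the
#' effective optical path set by the DRS fibre offset.
#'
#' @param sample One row of a design tibble (needs `absorber_fraction`,
#'   `scatterer_fraction`).
#' @param instrument An [instrument_spec()].
#' @param source_wavelength A wavelength present in the instrument's
#'   source list (nm).
#' @param medium An [optical_medium()].
#' @return Reflectance signal in photodiode units (noiseless).
#' @export
diffuse_reflectance <- function(sample, instrument, source_wavelength,
                                medium = optical_medium()) {
  j <- require_source(instrument, source_wavelength)
  mu <- mu_eff_at(medium, source_wavelength,
                  sample$absorber_fraction[1], sample$scatterer_fraction[1])
  instrument$source_powers[j] * instrument$drs_gain *
    exp(-mu * instrument$sd_separation_drs)
}

#' Reflected excitation power reaching the fluorescence detection path
#'
#' The excitation light diffusely reflected back into the fluorescence
#' fibre (the light whose leakage through the dichroic stack produces the
#' crosstalk signal), in nW: source power times `reflex_gain`, attenuated
#' over the out-and-back fluorescence path.
#'
#' @inheritParams diffuse_reflectance
#' @return Power in nW (noiseless).
#' @export
reflected_excitation <- function(sample, instrument, source_wavelength,
                                 medium = optical_medium()) {
  j <- require_source(instrument, source_wavelength)
  mu <- mu_eff_at(medium, source_wavelength,
                  sample$absorber_fraction[1], sample$scatterer_fraction[1])
  instrument$source_powers[j] * instrument$reflex_gain *
    exp(-2 * mu * instrument$sd_separation_fluor)
}

#' Noiseless fluorescence voltage for one (source, channel) pair
#'
#' Sums over the fluorophore panel: source power x concentration x
#' molar response x Gaussian excitation efficiency at the source
#' wavelength x quantum yield x fraction of the Gaussian emission band
#' inside the channel passband, attenuated once at the excitation and
#' once at the emission wavelength over the fluorescence path, and
#' converted to volts by the SiPMT gain. Exactly linear in each
#' concentration; saturation is applied later, at acquisition.
#'
#' @inheritParams diffuse_reflectance
#' @param channel_center A wavelength present in the instrument's channel
#'   list (nm).
#' @param fluorophores A fluorophore table, see [default_fluorophores()].
#' @return Pre-noise, pre-clip voltage.
#' @export
fluorescence_voltage <- function(sample, instrument, source_wavelength,
                                 channel_center,
                                 fluorophores = default_fluorophores(),
                                 medium = optical_medium()) {
  j <- require_source(instrument, source_wavelength)
  require_channel(instrument, channel_center)
  fluorophores <- validate_fluorophores(fluorophores)
  conc <- sample_conc(sample, fluorophores)
  af <- sample$absorber_fraction[1]
  sf <- sample$scatterer_fraction[1]
  mu_x <- mu_eff_at(medium, source_wavelength, af, sf)
  mu_m <- mu_eff_at(medium, channel_center, af, sf)
  atten <- exp(-(mu_x + mu_m) * instrument$sd_separation_fluor)
  per_fluor <- conc * fluorophores$molar_response *
    excitation_efficiency(fluorophores$ex_peak, fluorophores$ex_fwhm,
                          source_wavelength) *
    fluorophores$quantum_yield *
    emission_fraction(fluorophores$em_peak, fluorophores$em_fwhm,
                      channel_center, instrument$channel_fwhm)
  instrument$source_powers[j] * sum(per_fluor) * atten * instrument$gain
}

# one lognormal flash factor with mean 1 and the requested CV
rflash <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one raw acquisition frame
#'
#' Produces the 9-state acquisition for one phantom: a dark state (ambient
#' background plus read noise on every detector) followed by one state per
#' source. In each illuminated state the SiPMT channel voltages are
#' `clip(flash * (fluorescence + crosstalk * reflected excitation * gain)
#' + ambient + read noise)` — clipped only at the top, at `v_max` — and
#' the photodiode reads `flash * DRS + ambient + read noise`, where the
#' per-state flash factor is shared by all detectors of that state (the
#' photodiode and SiPMTs see the same flash).
#'
#' @inheritParams fluorescence_voltage
#' @param seed Integer seed for this frame's noise draws.
#' @return A long tibble with columns `sample_id`, `state` (`"dark"` or
#'   the source wavelength in nm), `detector` (`"pd"` or `"ch<nm>"`),
#'   `value`, `seed`.
#' @export
simulate_frame <- function(sample, instrument = instrument_spec(),
                           fluorophores = default_fluorophores(),
                           medium = optical_medium(), seed = 1) {
  set.seed(as.integer(seed))
  src <- instrument$source_wavelengths
  ch <- instrument$channel_centers
  n_src <- length(src)
  n_ch <- length(ch)
  det_names <- c("pd", paste0("ch", ch))

  flash <- rflash(n_src, instrument$noise_source_cv)
  read_noise <- matrix(stats::rnorm((n_src + 1) * (n_ch + 1),
                                    sd = instrument$noise_detector_sd),
                       nrow = n_src + 1)

  rows <- vector("list", n_src + 1)
  # dark state: ambient + read noise on every detector
  rows[[1]] <- tibble::tibble(
    sample_id = sample$sample_id[1],
    state = "dark",
    detector = det_names,
    value = instrument$ambient_level + read_noise[1, ]
  )
  for (j in seq_len(n_src)) {
    drs <- diffuse_reflectance(sample, instrument, src[j], medium)
    reflex <- reflected_excitation(sample, instrument, src[j], medium)
    fl <- vapply(ch, function(cc) {
      fluorescence_voltage(sample, instrument, src[j], cc, fluorophores, medium)
    }, numeric(1))
    sipmt <- flash[j] * (fl + instrument$crosstalk[, j] * reflex * instrument$gain) +
      instrument$ambient_level + read_noise[j + 1, -1]
    sipmt <- pmin(sipmt, instrument$v_max)
    pd <- min(flash[j] * drs + instrument$ambient_level + read_noise[j + 1, 1],
              instrument$pd_max)
    rows[[j + 1]] <- tibble::tibble(
      sample_id = sample$sample_id[1],
      state = as.character(src[j]),
      detector = det_names,
      value = unname(c(pd, sipmt))
    )
  }
  out <- dplyr::bind_rows(rows)
  out$seed <- as.integer(seed)
  out
}

#' Simulate raw frames for a whole phantom design
#'
#' Runs [simulate_frame()] over every row of a design table. Each sample
#' draws its noise from its own stream, derived deterministically from
#' the global seed and the sample index, so extending the design does not
#' perturb the draws of earlier samples.
#'
#' @param design A design tibble, e.g. [factorial_design()].
#' @inheritParams simulate_frame
#' @return A long tibble of frames (all samples stacked); the `seed`
#'   column records the global seed.
#' @examples
#' frames <- simulate_frames(absorber_sweep_design()[1:2, ], seed = 1)
#' dplyr::count(frames, sample_id)
#' @export
simulate_frames <- function(design, instrument = instrument_spec(),
                            fluorophores = default_fluorophores(),
                            medium = optical_medium(), seed = 1) {
  stopifnot(is.data.frame(design), nrow(design) >= 1,
            !anyDuplicated(design$sample_id))
  seed <- as.integer(seed)
  out <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    frame_seed <- (abs(as.numeric(seed)) + i * 1000003) %% .Machine$integer.max
    simulate_frame(design[i, ], instrument, fluorophores, medium,
                   seed = frame_seed)
  })
  out$seed <- seed
  out
}
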