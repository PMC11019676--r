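# Shared fixtures: small instruments and cached simulations, all built in
# code at test time.

# three-wavelength instrument for fast structural tests
tiny_instrument <- function(...) {
  wl <- c(340, 470, 590)
  instrument_spec(source_wavelengths = wl, source_powers = c(1, 1, 1),
                  channel_centers = wl,
                  crosstalk = default_crosstalk(wl, wl), ...)
}

# single blank sample at the reference base composition
blank_sample <- function() {
  tibble::tibble(sample_id = "B001", nadh = 0, fad = 0, ppix = 0,
                 absorber_fraction = 0.5, scatterer_fraction = 4)
}

nadh_only_sample <- function(conc = 50) {
  s <- blank_sample()
  s$nadh <- conc
  s
}

# the full noisy factorial run is shared by several acceptance checks;
# simulate and cross-validate it once per test session
.run_cache <- new.env(parent = emptyenv())

factorial_noisy_cv <- function() {
  if (is.null(.run_cache$cv)) {
    design <- factorial_design()
    inst <- instrument_spec()
    frames <- simulate_frames(design, inst, seed = 1)
    features <- assemble_features(subtract_background(frames, inst), inst)
    .run_cache$design <- design
    .run_cache$cv <- pls_loocv(features, as.matrix(design[c("nadh", "fad", "ppix")]),
                               ncomp_max = 8, components = 4)
  }
  list(design = .run_cache$design, cv = .run_cache$cv)
}
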