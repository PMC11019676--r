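# eemphantom

Quantifying fluorophore concentrations in turbid media from sparse
excitation–emission measurements is a core problem in optical surgical
guidance: intraoperative probes read out the autofluorescence of the
metabolic cofactors NADH and FAD and of protoporphyrin IX (PpIX, the
5-ALA metabolite that accumulates in tumour cells), but the raw
fluorescence they collect is distorted by tissue absorption and
scattering, source-power fluctuation, ambient light, detector crosstalk
and saturation.

`eemphantom` provides, in one tidyverse-native R package:

* a **forward simulator** of a multi-spectral fibre-probe instrument —
  eight sources (300–680 nm), eight SiPMT detection channels, a
  photodiode for diffuse reflectance (DRS), illumination-leakage
  crosstalk, lognormal per-flash source fluctuation, additive read
  noise, ambient background, and hard detector saturation at 5 V —
  measuring liquid tissue phantoms (intralipid + India ink +
  fluorophores) under a diffusion-theory attenuation closure
  `μ_eff = sqrt(3 μ_a (μ_a + μ_s'))`;
* the **inverse analysis chain**: ambient-background subtraction from a
  dark state, masking of anti-Stokes (channel < source) wavelength
  pairs, reflectance normalisation `nFL = FL / (Ex · Em)` (with `Ex`,
  `Em` the DRS intensities at the excitation and emission wavelengths),
  and multi-response NIPALS PLS2 regression with leave-one-out
  cross-validation and MSE-elbow component selection;
* **diagnostics**: crosstalk characterisation on a fluorophore-free
  standard, excitation-specificity slopes from dilution series,
  cross-fluorophore prediction independence on factorial designs, and
  detector linear-range estimation.

For whom: researchers developing or validating probe-based fluorescence
quantification pipelines who need a controlled, reproducible test bed
with known ground truth.

## Worked example

Simulate the 125-phantom mixed-fluorophore factorial (five levels each of
NADH, FAD and PpIX at fixed absorber/scatterer), run the full chain and
select the component count by the MSE elbow:

```r
library(eemphantom)

report <- run_pipeline(factorial_design(), seed = 42, components = "auto")
report
#> <eem_report> n = 125, drs-normalised, selected k = 4
#> # A tibble: 3 × 2
#>   response    r2
#>   <chr>    <dbl>
#> 1 nadh     1.000
#> 2 fad      0.995
#> 3 ppix     1.000
```

The elbow rule lands on four PLS components: three latent concentration
axes plus one component absorbing the nonlinearity introduced by the
channels that saturate at high signal. The `r2` column is the
coefficient of determination between the leave-one-out predicted and
true concentrations, per fluorophore; values near 1 mean the chain
recovers each concentration essentially perfectly despite noise,
crosstalk and four saturated channels per acquisition.
`autoplot(report)` draws predicted-versus-true panels and
`autoplot(report$cv)` the MSE-versus-components curve.

Characterising crosstalk on a fluorophore-free standard (run at reduced
power so the matched channels stay in the linear range) recovers the
configured leakage exactly:

```r
inst <- quiet_instrument(instrument_spec(), power_scale = 0.05)
blank <- factorial_design()[125, ]   # the zero-fluorophore phantom
ct <- crosstalk_matrix(simulate_frames(blank, inst, seed = 1), inst)
dplyr::filter(ct, source == 340, channel %in% c(470, 680))
#> # A tibble: 2 × 4
#>   source channel percent flagged
#>    <dbl>   <dbl>   <dbl> <lgl>
#> 1    340     470   0.001 FALSE
#> 2    340     680   0.002 FALSE
```

i.e. 1×10⁻³ % leakage into the NADH emission channel and 2×10⁻³ % into
the PpIX emission channel under 340 nm illumination.

## Package tour

| area | functions |
|---|---|
| phantom designs | `factorial_design()`, `absorber_sweep_design()`, `dilution_series_design()` |
| optics | `optical_medium()`, `reduced_scattering()`, `absorption_coefficient()`, `effective_attenuation()` |
| forward model | `instrument_spec()`, `default_fluorophores()`, `simulate_frames()`, `diffuse_reflectance()`, `fluorescence_voltage()` |
| inverse chain | `subtract_background()`, `mask_pairs()`, `normalize_drs()`, `assemble_features()` |
| regression | `fit_pls()`, `pls_loocv()`, `select_components()`, `r_squared()`, `tidy()`/`glance()`/`augment()` |
| diagnostics | `crosstalk_matrix()`, `specificity_slopes()`, `independence_check()`, `linearity_range()` |
| workflow & I/O | `run_pipeline()`, `read_frames()`/`write_frames()`, `read_instrument()`/`write_instrument()` |

The methods vignette (`vignettes/phantom-recovery.Rmd`) documents the
forward model, every tunable parameter with units and defaults, and the
numerical choices in the regression.
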