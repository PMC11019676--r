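---
title: "Recovering fluorophore concentrations from simulated fibre-probe EEM/DRS measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering fluorophore concentrations from simulated fibre-probe EEM/DRS measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eemphantom)
library(dplyr)
```

`eemphantom` is a test bed for probe-based fluorescence quantification in
turbid media. It couples a parametric forward model of a multi-spectral
fibre-probe instrument — excitation–emission matrix (EEM) acquisition on
SiPMT detectors plus photodiode diffuse reflectance (DRS) — to the
inverse chain that estimates fluorophore concentrations: background
subtraction, wavelength-pair masking, reflectance normalisation and
multi-response PLS regression under leave-one-out cross-validation
(LOOCV). Because the simulator knows the ground truth, every stage of
the chain can be validated quantitatively.

## The forward model

### Phantom optics

A liquid phantom is an aqueous mixture of intralipid (scatterer), India
ink (absorber) and up to three fluorophores: NADH, FAD and
protoporphyrin IX (PpIX). Optical properties are anchored at 470 nm:
with the default base composition (4 % of the 20 % intralipid stock,
0.5 % of the ink stock) the reduced scattering coefficient is
$\mu_s'(470) = 8.3\ \mathrm{cm^{-1}}$ and the absorption coefficient
$\mu_a(470) = 0.32\ \mathrm{cm^{-1}}$, values representative of cortical
tissue. Scattering follows the intralipid power law
$\mu_s'(\lambda) = 8.3\,(\lambda/470)^{-b}$ with $b = 2.4$ by default,
and scales linearly with the scatterer fraction. The ink spectrum is
flat by default — India ink is nearly grey over 300–700 nm — and scales
linearly with the absorber fraction; a spectral shape function can be
supplied.

Light transport is closed with the diffusion-theory effective
attenuation coefficient
$$\mu_{\mathrm{eff}} = \sqrt{3\,\mu_a(\mu_a + \mu_s')},$$
applied as a modified Beer–Lambert factor $e^{-\mu_{\mathrm{eff}}\rho}$
over fixed effective path lengths: $\rho_{\mathrm{drs}} = 0.1$ cm for
the DRS fibre (offset ≈ 1 mm from the sources, sampling a longer path)
and $\rho_{\mathrm{fl}} = 0.05$ cm for the fluorescence fibre, applied
once at the excitation and once at the emission wavelength. This is the
simplest closure that reproduces the attenuation phenomenology the
analysis chain must cope with; Monte-Carlo photon transport is
deliberately out of scope. The choice $\rho_{\mathrm{drs}} >
\rho_{\mathrm{fl}}$ matters qualitatively: the DRS reading is attenuated
more strongly than the fluorescence it is meant to correct, so the
normalised signal *over*-estimates with increasing absorber — the
residual absorber dependence examined below.

### Fluorescence and reflectance signals

Fluorophore spectra are Gaussian: excitation peaks at 340 (NADH), 450
(FAD) and 405 nm (PpIX) with 60 nm FWHM, emission peaks at 460, 525 and
635 nm with 80 nm FWHM — literature-typical shapes. The noiseless SiPMT
voltage for source $s$ and channel $c$ is

$$V_{s,c} = S_s \, g \, e^{-(\mu_{\mathrm{eff}}(\lambda_s)+\mu_{\mathrm{eff}}(\lambda_c))\rho_{\mathrm{fl}}}
\sum_f c_f \, m_f \, \varepsilon_f(\lambda_s)\, \phi_f \, \Phi_f(c),$$

with $S_s$ the source power, $g$ the detector gain (V/nW), $c_f$ the
concentration (µg/ml), $m_f$ the molar response (nW per µg/ml at the
excitation peak), $\varepsilon_f$ the Gaussian excitation efficiency,
$\phi_f$ the quantum yield and $\Phi_f(c)$ the fraction of the emission
band inside the channel passband (25 nm FWHM). The signal is exactly
linear in each concentration; all nonlinearity enters later, at the
detector. The photodiode DRS reading is
$S_s\, e^{-\mu_{\mathrm{eff}}(\lambda_s)\rho_{\mathrm{drs}}}$, and the
reflected excitation light reaching the fluorescence detection path is
$S_s\, G_r\, e^{-2\mu_{\mathrm{eff}}(\lambda_s)\rho_{\mathrm{fl}}}$ nW
with $G_r = 60$ by default; its leakage into channel $i$ under source
$j$ is the crosstalk matrix entry $L_{ij}$, equal to 1 on the matched
diagonal and pinned to the characterised values
$10^{-5}$, $2.5\times10^{-4}$ and $2\times10^{-5}$ for the
(340 → 470), (440 → 590) and (340 → 680) pairs.

### Noise, background and saturation

Each acquisition has nine states: one dark, then one per source. Per
illuminated state a single lognormal flash factor (mean 1, CV 0.02 by
default) multiplies the true optical signal on *every* detector of that
state — photodiode and SiPMTs see the same flash, which is what makes
reflectance normalisation cancel source fluctuation. Additive Gaussian
read noise (sd $10^{-4}$ V) and a constant ambient background (0.05 V,
present in the dark state too) complete the model. SiPMT outputs are
hard-clipped at $V_{\max} = 5$ V; there is no lower clip, so background
subtraction may legitimately produce small negative values. The gain
maps the top of the detector's linear range (0.03–37 nW) onto the 5 V
ceiling.

### Calibration of the default response scales

The molar responses, source powers and reflected-excitation gain were
set together so that the simulated acquisitions reproduce the regimes a
high-sensitivity SiPMT array actually encounters: the three LED sources
(300, 340, 590 nm) and the de-rated 390 nm laser are weaker than the
remaining lasers, and with $G_r = 60$ the reflected excitation on the
four strong-laser matched channels (440, 470, 515, 680 nm) exceeds the
ceiling in **every** acquisition — four of the eight channels saturate
at 5 V, exactly the situation a DRS-scale return creates for a detector
tuned to picowatt fluorescence. The molar responses place the matched
fluorescence readouts of NADH and FAD at their top concentrations
slightly above the ceiling as well, so high-concentration phantoms
clip on an informative channel, while neighbouring channels that catch
the emission tail stay linear. These scales were fixed from the forward
reasoning above, before any recovery experiment was run.

### What the generator does and does not emulate

Emulated: linear concentration response per fluorophore; attenuation by
$\mu_a$/$\mu_s'$ at excitation and emission wavelengths; residual
absorber dependence after normalisation; illumination-leakage
crosstalk; detector saturation; ambient background common to all
states; shared per-flash source fluctuation. Not emulated: real
(non-Gaussian, tabulated) fluorophore spectra and their pH/binding
shifts, photobleaching kinetics, dynamically changing ambient light,
wavelength-calibration error, probe–tissue contact variability, and
radiative transport beyond the diffusion closure. Passing tests
therefore demonstrate that the *analysis chain* is correct and robust
to the modelled distortions — not that the model captures every
property of real tissue measurements.

## The inverse chain

**Background subtraction.** The dark state's per-detector values are
subtracted from the same detector in all illuminated states. This is
exactly invariant to any constant offset added to a whole frame
(property-tested), and a zero dark frame is the identity.

**Masking.** Channels below the source wavelength cannot carry
(Stokes-shifted) fluorescence and are dropped. For the eight shared
wavelengths this leaves $8+7+\dots+1 = 36$ (source, channel) pairs, in
deterministic source-major order. The 300 nm pairs are retained by
default (a `drop_sources` argument exists for instruments whose UV
source is unusable).

**Normalisation.** Each masked value is divided by the product of the
DRS intensities at the pair's excitation and emission wavelengths,
$n\mathrm{FL} = \mathrm{FL}/(Ex \cdot Em)$ — e.g. the NADH readout uses
DRS at 340 nm ($Ex$) and at 470 nm ($Em$). The normalisation is defined
for every pair because each channel center coincides with a source
wavelength, the only reading consistent with a full 36-column
normalised matrix. Algebraically, scaling one source's power by $s$
multiplies that pair's flash-coupled FL and $Ex$ by $s$ and (for the
diagonal pair) $Em$ as well, so the diagonal feature scales by $1/s$
and off-diagonal features are invariant; both identities are asserted
exactly in the tests. Samples with non-positive DRS yield invalid
features, carried as `NA` with a warning and excluded from fits.
Saturated raw values are *not* imputed — they are flagged and carried
through, as a real analysis would have to do.

**Regression.** `fit_pls()` implements NIPALS PLS2 on mean-centered
data. Numerical choices: convergence tolerance $10^{-10}$ on the score
vector, at most 500 iterations per component, deterministic
initialisation from the residual response column with the largest sum
of squares (no random starts, so fits are bit-reproducible), and
deflation of both blocks so one fit contains all nested sub-models.
Predictors are centered but not autoscaled by default: after
normalisation all 36 features share one scale, and autoscaling would
inflate pure-noise channels; `scale = TRUE` is available. At full rank
PLS reproduces ordinary least squares, which the tests assert against
`lm()`, and predictions agree with an independent PLS implementation
(mixOmics) to $10^{-6}$ relative.

**Model selection.** LOOCV refits the model $n$ times; the MSE curve is
the mean squared error over rows and responses, responses on their
natural concentration scales (so the widest-ranging fluorophore
dominates — a deliberate, documented convention; autoscaled responses
would weight them equally). The elbow rule selects the smallest $k$
whose relative improvement $(\mathrm{MSE}_k -
\mathrm{MSE}_{k+1})/\mathrm{MSE}_1$ falls below $\tau = 0.01$. On the
125-phantom factorial with default noise this lands on **four**
components: three latent concentration axes plus one component
absorbing the saturation kink. In the detector's linear range (all
channels unsaturated, noise off) three components recover all three
concentrations with LOOCV $R^2 \ge 0.999$, confirming that the fourth
component is the saturation response, not a property of the chain.
Recovery quality is reported as the coefficient of determination
$1 - SSE/SST$ on LOOCV predictions per response; the squared Pearson
correlation is a near-identical alternative obtainable from
`augment()`.

## Diagnostics

`crosstalk_matrix()` normalises a fluorophore-free standard's
background-subtracted channel values by the matched-channel value per
source — percentages relative to the matched (source = channel) entry,
the convention that makes "leakage into fluorescence channels"
well-defined. Characterisation measurements should be run at reduced
power (`quiet_instrument(power_scale = ...)`, the software analogue of a
neutral-density filter) so the matched channels stay linear; saturated
references are flagged rather than mis-normalised. On noiseless frames
the forward–inverse round trip recovers the configured leakage to
machine precision.

`specificity_slopes()` regresses intensity on concentration per
(fluorophore, pair) and flags slopes beyond three standard errors of
zero — the operationalisation of "no significant concentration
dependence" off the absorption band. `independence_check()` regresses
LOOCV predictions of each fluorophore on the true concentration of every
other; on a balanced factorial the cross slopes are exactly zero for any
prediction that depends only on its own target, so non-zero flagged
slopes indicate genuine leakage between fluorophore estimates.
`linearity_range()` fits the central decade of a power sweep and
returns the widest contiguous range within 5 % of that line (detector
datasheets state the range, not the acceptance criterion; 5 % is this
package's choice).

## Design choices on genuinely open points

* **Scatterer "20 %".** The absorber-sweep design holds the scatterer
  at a constant *final* fraction of 4 % of the 20 % stock, matching the
  mixed-fluorophore set; both the fraction and the stock anchoring are
  configurable in `optical_medium()`.
* **PpIX matched pair.** The instrument convention pairs PpIX with
  (340, 680) even though its Soret band near 405 nm means the 390/440 nm
  sources excite it more strongly; the default follows the instrument
  convention and `specificity_slopes()` makes the stronger off-pair
  response visible rather than hiding it.
* **Elbow operationalisation.** "MSE no longer changes appreciably" is
  made concrete as the relative-improvement threshold $\tau$; 0.01 is
  the default and monotonicity in $\tau$ is property-tested.
* **Responses of constant concentration** (e.g. the absent fluorophores
  of a single-fluorophore series) are dropped from the fit rather than
  producing undefined $R^2$.

## Problem sizes and runtime

The package's standard experiment is the full 125-sample factorial with
36 features: simulation plus LOOCV over eight candidate component
counts completes in a few seconds on one core, and the whole test suite
(including two full factorial simulations) runs in well under a minute.
The structural tests use a three-wavelength miniature instrument for
speed.

## Known limitations

The diffusion closure with fixed effective paths is a first-order
stand-in for probe-geometry-dependent transport; absolute signal levels
are arbitrary-unit, only their ratios and trends are meaningful. The
Gaussian spectra underestimate the long red tails of real fluorophores,
which would increase inter-channel bleed. Saturated features are kept
as-is, which is faithful to practice but means concentration ranges far
beyond the calibrated ones degrade gracefully rather than error out.
LOOCV on strongly structured factorials is optimistic relative to
held-out generalisation on independently prepared phantoms.
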