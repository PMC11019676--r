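Package: eemphantom
Title: Simulation and Analysis of Multi-Spectral Fluorescence and Diffuse
    Reflectance Phantom Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of a fibre-probe instrument that measures
    diffuse reflectance (DRS) and multi-channel autofluorescence of liquid
    tissue phantoms containing NADH, FAD and protoporphyrin IX, together
    with the inverse analysis chain that recovers fluorophore
    concentrations: ambient-background subtraction, masking of
    uninformative excitation/detection wavelength pairs, reflectance-based
    normalisation of fluorescence, and multi-response partial least
    squares regression with leave-one-out cross-validation and
    MSE-elbow component selection. Includes diagnostics for detector
    crosstalk, excitation specificity, prediction independence and
    detector linear range.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
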