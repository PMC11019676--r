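#' Mixed-fluorophore phantom design (full factorial, n = 125)
#'
#' The full factorial of five concentration levels per fluorophore —
#' NADH \{100, 50, 25, 12.5, 0\}, FAD \{10, 5, 2.5, 1.25, 0\} and PpIX
#' \{10, 5, 2.5, 1.25, 0\} ug/ml (halving dilution series covering the
#' tissue-typical range) — at fixed base composition: 0.5 % ink stock as
#' absorber, 4 % intralipid stock as scatterer.
#'
#' @return A tibble with 125 rows and columns `sample_id`, `nadh`, `fad`,
#'   `ppix` (ug/ml), `absorber_fraction`, `scatterer_fraction` (%).
#' @examples
#' nrow(factorial_design())
#' @export
factorial_design <- function() {
  d <- tidyr::expand_grid(
    nadh = c(100, 50, 25, 12.5, 0),
    fad = c(10, 5, 2.5, 1.25, 0),
    ppix = c(10, 5, 2.5, 1.25, 0)
  )
  tibble::tibble(
    sample_id = sprintf("P%03d", seq_len(nrow(d))),
    d,
    absorber_fraction = 0.5,
    scatterer_fraction = 4
  )
}

#' Absorber-sweep phantom design (FAD x ink, n = 20)
#'
#' Single-fluorophore set used to probe the residual absorber dependence
#' of normalised fluorescence: five FAD levels spanning 0--10 ug/ml
#' crossed with four absorber fractions spanning 0.5--4 %, at constant
#' scatterer fraction.
#'
#' @param fad_levels FAD concentrations (ug/ml).
#' @param absorber_fractions Ink stock volume fractions (%).
#' @param scatterer_fraction Intralipid stock volume fraction (%).
#' @return A tibble with `length(fad_levels) * length(absorber_fractions)`
#'   rows, same columns as [factorial_design()] (NADH and PpIX at zero).
#' @export
absorber_sweep_design <- function(fad_levels = c(0, 1.25, 2.5, 5, 10),
                        absorber_fractions = c(0.5, 1, 2, 4),
                        scatterer_fraction = 4) {
  d <- tidyr::expand_grid(fad = fad_levels,
                          absorber_fraction = absorber_fractions)
  tibble::tibble(
    sample_id = sprintf("A%03d", seq_len(nrow(d))),
    nadh = 0,
    fad = d$fad,
    ppix = 0,
    absorber_fraction = d$absorber_fraction,
    scatterer_fraction = scatterer_fraction
  )
}

#' Single-fluorophore dilution series
#'
#' Replicated dilution series of one fluorophore at the base phantom
#' composition, used for excitation-specificity characterisation
#' (slope of intensity versus concentration per wavelength pair).
#'
#' @param fluorophore One of `"nadh"`, `"fad"`, `"ppix"`.
#' @param levels Concentration levels (ug/ml); defaults to the factorial
#'   levels for that fluorophore.
#' @param n_rep Replicates per level.
#' @return A design tibble in the same shape as [factorial_design()], with a
#'   `replicate` column.
#' @export
dilution_series_design <- function(fluorophore = c("nadh", "fad", "ppix"),
                                   levels = NULL, n_rep = 5) {
  fluorophore <- match.arg(fluorophore)
  if (is.null(levels)) {
    levels <- if (fluorophore == "nadh") c(0, 12.5, 25, 50, 100)
              else c(0, 1.25, 2.5, 5, 10)
  }
  d <- tidyr::expand_grid(conc = levels, replicate = seq_len(n_rep))
  out <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(nrow(d))),
    nadh = 0, fad = 0, ppix = 0,
    absorber_fraction = 0.5,
    scatterer_fraction = 4,
    replicate = d$replicate
  )
  out[[fluorophore]] <- d$conc
  out
}

design_responses <- function(design) {
  intersect(c("nadh", "fad", "ppix"), names(design))
}
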