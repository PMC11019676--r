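#' Crosstalk matrix from a fluorophore-free standard
#'
#' Characterises illumination leakage: on frames acquired from a
#' zero-fluorescence standard, each channel's background-subtracted value
#' under each source is expressed as a percentage of the matched channel
#' (the channel whose center equals the source wavelength). Matched
#' entries are 100 % by construction. Run the standard at reduced source
#' power (see [quiet_instrument()]) so the matched channels stay inside
#' the detector's linear range; entries whose matched value is
#' non-positive or saturated are flagged and returned as `NA`.
#'
#' @param frames Raw frames of one or more fluorophore-free samples.
#' @param instrument The [instrument_spec()] used for acquisition.
#' @return A tibble of class `"crosstalk_report"` with columns `source`,
#'   `channel`, `percent` and `flagged`.
#' @export
crosstalk_matrix <- function(frames, instrument) {
  corrected <- subtract_background(frames, instrument)
  vals <- corrected |>
    dplyr::filter(grepl("^ch", .data$detector)) |>
    dplyr::mutate(source = as.numeric(.data$state),
                  channel = as.numeric(sub("^ch", "", .data$detector))) |>
    dplyr::group_by(.data$source, .data$channel) |>
    dplyr::summarise(value = mean(.data$value),
                     saturated = any(.data$saturated), .groups = "drop")
  matched <- vals |>
    dplyr::filter(.data$channel == .data$source) |>
    dplyr::select("source", ref = "value", ref_saturated = "saturated")
  if (nrow(matched) < length(unique(vals$source))) {
    stop("every source needs a matched channel (center == source wavelength)",
         call. = FALSE)
  }
  out <- vals |>
    dplyr::left_join(matched, by = "source") |>
    dplyr::mutate(flagged = .data$ref <= 0 | .data$ref_saturated,
                  percent = ifelse(.data$flagged, NA_real_,
                                   100 * .data$value / .data$ref)) |>
    dplyr::select("source", "channel", "percent", "flagged") |>
    dplyr::arrange(.data$source, .data$channel)
  class(out) <- c("crosstalk_report", class(out))
  out
}

#' Excitation-specificity slopes from single-fluorophore dilution series
#'
#' For each (fluorophore, source, channel) combination, fits mean
#' intensity against concentration by least squares and reports slope,
#' intercept and slope standard error. Pairs whose slope differs from
#' zero by more than three standard errors are flagged as responsive: a
#' fluorophore should respond only where the excitation wavelength
#' overlaps its absorption band.
#'
#' @param intensities Long tibble with columns `fluorophore`,
#'   `concentration`, `source`, `channel`, `value` (replicates allowed;
#'   at least two, ideally five or more, distinct concentration levels
#'   per series).
#' @return A tibble of class `"slope_report"`: `fluorophore`, `source`,
#'   `channel`, `slope`, `intercept`, `std_error`, `responsive`.
#' @export
specificity_slopes <- function(intensities) {
  stopifnot(all(c("fluorophore", "concentration", "source", "channel",
                  "value") %in% names(intensities)))
  n_lev <- intensities |>
    dplyr::distinct(.data$fluorophore, .data$concentration) |>
    dplyr::count(.data$fluorophore)
  if (any(n_lev$n < 2)) {
    stop("each fluorophore series needs at least two distinct ",
         "concentration levels", call. = FALSE)
  }
  out <- intensities |>
    dplyr::group_by(.data$fluorophore, .data$source, .data$channel) |>
    dplyr::group_modify(function(df, key) {
      fit <- stats::lm(value ~ concentration, data = df)
      cf <- summary(fit)$coefficients
      tibble::tibble(slope = cf["concentration", "Estimate"],
                     intercept = cf["(Intercept)", "Estimate"],
                     std_error = cf["concentration", "Std. Error"])
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(responsive = abs(.data$slope) > 3 * .data$std_error)
  class(out) <- c("slope_report", class(out))
  out
}

#' Cross-fluorophore prediction independence
#'
#' Regresses the cross-validated prediction of each fluorophore on the
#' true concentration of every fluorophore (including itself). On a
#' balanced factorial design the cross slopes are exactly zero whenever
#' each prediction depends only on its own target; slopes more than three
#' standard errors from zero are flagged. The self slope should be close
#' to one when recovery is good.
#'
#' @param cv A [pls_loocv()] result from a factorial design.
#' @param truth Data frame of true concentrations, one column per
#'   response in `cv` (a `sample_id` column is ignored).
#' @return A tibble: `predicted`, `truth_var`, `slope`, `std_error`,
#'   `flagged`.
#' @export
independence_check <- function(cv, truth) {
  stopifnot(inherits(cv, "pls_cv"))
  responses <- colnames(cv$predictions)
  tr <- as_numeric_matrix(truth[responses], "truth")
  stopifnot(nrow(tr) == nrow(cv$predictions))
  lev <- lapply(responses, function(r) sort(unique(tr[, r])))
  if (nrow(tr) != prod(lengths(lev))) {
    warning("design does not look like a full factorial; cross slopes are ",
            "not guaranteed zero by balance", call. = FALSE)
  }
  grid <- tidyr::expand_grid(predicted = responses, truth_var = responses)
  purrr::pmap_dfr(grid, function(predicted, truth_var) {
    fit <- stats::lm(cv$predictions[, predicted] ~ tr[, truth_var])
    cf <- summary(fit)$coefficients
    tibble::tibble(predicted = predicted, truth_var = truth_var,
                   slope = cf[2, "Estimate"], std_error = cf[2, "Std. Error"],
                   flagged = predicted != truth_var &
                     abs(cf[2, "Estimate"]) > 3 * cf[2, "Std. Error"])
  })
}

#' Linear input range of a detector sweep
#'
#' Given a monotone input-power sweep and the recorded outputs, fits a
#' least-squares line to the central decade of the sweep (in log input)
#' and returns the widest contiguous input range over which the output
#' stays within `deviation` (default 5 %) of that line. Saturated points
#' at the top and a noise floor at the bottom fall outside the returned
#' range.
#'
#' @param power Input powers (positive, strictly increasing), e.g. nW.
#' @param output Recorded outputs (same length, at least 4 points).
#' @param deviation Allowed relative deviation from the reference line.
#' @return A named numeric vector `c(min = , max = )` in input units.
#' @export
linearity_range <- function(power, output, deviation = 0.05) {
  stopifnot(length(power) == length(output), length(power) >= 4,
            all(power > 0), all(diff(power) > 0))
  lp <- log10(power)
  center <- (min(lp) + max(lp)) / 2
  in_window <- abs(lp - center) <= 0.5
  if (sum(in_window) < 2) {
    in_window <- rank(abs(lp - center), ties.method = "first") <= 2
  }
  ref <- stats::lm(output ~ power, subset = in_window)
  fitted_all <- stats::predict(ref, newdata = data.frame(power = power))
  ok <- abs(output - fitted_all) < deviation * abs(fitted_all)
  runs <- rle(ok)
  if (!any(runs$values)) stop("no linear region found", call. = FALSE)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  c(min = power[starts[best]], max = power[ends[best]])
}
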