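#' Subtract the ambient background recorded in the dark state
#'
#' Every acquisition includes one state measured without illumination.
#' Its per-detector values estimate the ambient background and are
#' subtracted from the same detector in every illuminated state; the dark
#' state is then dropped. Values may go slightly negative under read
#' noise — no floor is applied. If an instrument is supplied, values that
#' hit the saturation ceiling in the raw frame are flagged.
#'
#' @param frames Long frame tibble from [simulate_frames()] or
#'   [read_frames()] (columns `sample_id`, `state`, `detector`, `value`).
#' @param instrument Optional [instrument_spec()]; when given, a logical
#'   `saturated` column marks SiPMT values at or above `v_max` in the raw
#'   frame.
#' @return A long tibble of corrected illuminated states.
#' @export
subtract_background <- function(frames, instrument = NULL) {
  stopifnot(all(c("sample_id", "state", "detector", "value") %in% names(frames)))
  dark_n <- frames |>
    dplyr::filter(.data$state == "dark") |>
    dplyr::count(.data$sample_id, .data$detector)
  samples <- unique(frames$sample_id)
  if (!setequal(dark_n$sample_id, samples) || any(dark_n$n != 1)) {
    stop("each sample must have exactly one dark value per detector",
         call. = FALSE)
  }
  dark <- frames |>
    dplyr::filter(.data$state == "dark") |>
    dplyr::select("sample_id", "detector", dark = "value")
  out <- frames |>
    dplyr::filter(.data$state != "dark") |>
    dplyr::left_join(dark, by = c("sample_id", "detector"))
  if (!is.null(instrument)) {
    out$saturated <- grepl("^ch", out$detector) & out$value >= instrument$v_max
  }
  out$value <- out$value - out$dark
  dplyr::select(out, -"dark")
}

#' Informative (source, channel) wavelength pairs
#'
#' Detection channels whose passband lies below the excitation wavelength
#' cannot carry fluorescence (anti-Stokes) and are omitted. Retains, in
#' source-major ascending order, exactly the pairs with channel center at
#' or above the source wavelength; for k shared wavelengths this yields
#' k(k+1)/2 pairs (36 for the 8-wavelength instrument).
#'
#' @param source_wavelengths Strictly increasing source wavelengths (nm).
#' @param channel_centers Strictly increasing channel centers (nm).
#' @return A tibble with columns `source` and `channel`.
#' @examples
#' nrow(mask_pairs(c(300, 340, 390, 440, 470, 515, 590, 680),
#'                 c(300, 340, 390, 440, 470, 515, 590, 680)))  # 36
#' @export
mask_pairs <- function(source_wavelengths, channel_centers) {
  stopifnot(all(diff(source_wavelengths) > 0), all(diff(channel_centers) > 0))
  tidyr::expand_grid(source = source_wavelengths, channel = channel_centers) |>
    dplyr::filter(.data$channel >= .data$source)
}

#' Reflectance-normalised fluorescence
#'
#' Normalises a background-subtracted fluorescence reading by the product
#' of the diffuse-reflectance intensities at the excitation and emission
#' wavelengths, `nFL = FL / (Ex * Em)`, compensating source-intensity
#' fluctuation and medium attenuation at both wavelengths. Non-positive
#' `Ex` or `Em` make the feature invalid: `NA` is returned for those
#' entries.
#'
#' @param fl Fluorescence value(s) (V, background-subtracted).
#' @param ex DRS intensity at the excitation (source) wavelength.
#' @param em DRS intensity at the emission (channel) wavelength.
#' @return Normalised value(s); `NA` where `ex` or `em` is non-positive.
#' @examples
#' normalize_drs(6, 2, 3)  # 1
#' @export
normalize_drs <- function(fl, ex, em) {
  ifelse(ex > 0 & em > 0, fl / (ex * em), NA_real_)
}

feature_label <- function(source, channel) {
  sprintf("src%d_ch%d", as.integer(source), as.integer(channel))
}

#' Assemble the masked, normalised feature matrix
#'
#' Builds the n-samples-by-p-features table consumed by the regression:
#' one column per informative (source, channel) pair, in source-major
#' order. With `normalization = "drs"` each entry is the channel voltage
#' under the pair's source divided by the product of the photodiode DRS
#' readings at the source wavelength and at the source matching the
#' channel center (every channel center coincides with a source
#' wavelength in the default instrument — required for this
#' normalisation). Samples with any invalid (non-positive DRS) feature
#' keep their row with `NA`s and trigger a warning; downstream fits drop
#' them.
#'
#' @param corrected Output of [subtract_background()].
#' @param instrument The [instrument_spec()] used for acquisition.
#' @param normalization `"drs"` (reflectance-normalised) or `"none"`
#'   (raw background-subtracted voltages).
#' @param drop_sources Optional source wavelengths to exclude from the
#'   feature set (e.g. a weak UV source).
#' @return A tibble: `sample_id` plus one `src<nm>_ch<nm>` column per
#'   retained pair, rows in first-appearance order of the input.
#' @export
assemble_features <- function(corrected, instrument,
                              normalization = c("drs", "none"),
                              drop_sources = NULL) {
  normalization <- match.arg(normalization)
  pairs <- mask_pairs(instrument$source_wavelengths, instrument$channel_centers)
  if (!is.null(drop_sources)) {
    pairs <- dplyr::filter(pairs, !.data$source %in% drop_sources)
  }
  if (normalization == "drs" &&
      !all(pairs$channel %in% instrument$source_wavelengths)) {
    stop("DRS normalisation needs every channel center to match a source ",
         "wavelength (its Em reading is the DRS at that source)",
         call. = FALSE)
  }

  sipmt <- corrected |>
    dplyr::filter(grepl("^ch", .data$detector)) |>
    dplyr::mutate(source = as.numeric(.data$state),
                  channel = as.numeric(sub("^ch", "", .data$detector))) |>
    dplyr::select("sample_id", "source", "channel", fl = "value")
  pd <- corrected |>
    dplyr::filter(.data$detector == "pd") |>
    dplyr::mutate(wavelength = as.numeric(.data$state)) |>
    dplyr::select("sample_id", "wavelength", drs = "value")

  long <- pairs |>
    dplyr::inner_join(sipmt, by = c("source", "channel")) |>
    dplyr::left_join(dplyr::rename(pd, ex = "drs"),
                     by = c("sample_id", source = "wavelength")) |>
    dplyr::left_join(dplyr::rename(pd, em = "drs"),
                     by = c("sample_id", channel = "wavelength"))
  long$value <- if (normalization == "drs") {
    normalize_drs(long$fl, long$ex, long$em)
  } else {
    long$fl
  }
  bad <- unique(long$sample_id[is.na(long$value)])
  if (length(bad)) {
    warning("invalid (non-positive DRS) features; samples carried with NA: ",
            paste(bad, collapse = ", "), call. = FALSE)
  }

  long |>
    dplyr::mutate(label = factor(feature_label(.data$source, .data$channel),
                                 levels = feature_label(pairs$source, pairs$channel)),
                  sample_id = factor(.data$sample_id,
                                     levels = unique(corrected$sample_id))) |>
    dplyr::select("sample_id", "label", "value") |>
    tidyr::pivot_wider(names_from = "label", values_from = "value",
                       names_expand = TRUE) |>
    dplyr::arrange(.data$sample_id) |>
    dplyr::mutate(sample_id = as.character(.data$sample_id))
}

#' Numeric feature matrix from an assembled feature tibble
#'
#' @param features Output of [assemble_features()].
#' @return A numeric matrix with sample ids as row names.
#' @export
feature_matrix <- function(features) {
  m <- as.matrix(features[setdiff(names(features), "sample_id")])
  rownames(m) <- features$sample_id
  m
}
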