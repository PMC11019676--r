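#' Write / read acquisition frames as long-format CSV
#'
#' The on-disk frame format is one row per (sample, state, detector)
#' value: columns `sample_id`, `state` (`dark` or the source wavelength
#' in nm), `detector` (`pd` or `ch<nm>`), `value`, `seed`. Values
#' round-trip at full double precision.
#'
#' @param frames A frame tibble from [simulate_frames()].
#' @param path CSV file path.
#' @return `write_frames()` returns `path` invisibly; `read_frames()`
#'   returns a validated frame tibble with samples in file order and
#'   states ordered dark-first then by wavelength.
#' @export
write_frames <- function(frames, path) {
  stopifnot(all(c("sample_id", "state", "detector", "value") %in% names(frames)))
  readr::write_csv(frames, path)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    state = readr::col_character(),
    detector = readr::col_character(),
    value = readr::col_double(),
    .default = readr::col_guess()
  )))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    stop("parse error at row(s) ", paste(unique(probs$row), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  if (anyNA(raw$value)) {
    stop("non-numeric value at row(s) ",
         paste(which(is.na(raw$value)), collapse = ", "), call. = FALSE)
  }
  bad_det <- setdiff(unique(raw$detector),
                     c("pd", grep("^ch[0-9]+$", unique(raw$detector), value = TRUE)))
  if (length(bad_det)) {
    stop("unknown detector label(s): ", paste(bad_det, collapse = ", "),
         call. = FALSE)
  }
  bad_state <- setdiff(unique(raw$state),
                       c("dark", grep("^[0-9.]+$", unique(raw$state), value = TRUE)))
  if (length(bad_state)) {
    stop("unknown state label(s): ", paste(bad_state, collapse = ", "),
         call. = FALSE)
  }
  dark <- raw |>
    dplyr::filter(.data$state == "dark") |>
    dplyr::distinct(.data$sample_id)
  missing_dark <- setdiff(unique(raw$sample_id), dark$sample_id)
  if (length(missing_dark)) {
    stop("sample(s) without a dark state: ",
         paste(missing_dark, collapse = ", "), call. = FALSE)
  }
  raw |>
    dplyr::mutate(
      sample_id = factor(.data$sample_id, levels = unique(.data$sample_id)),
      state_ord = ifelse(.data$state == "dark", -Inf,
                         suppressWarnings(as.numeric(.data$state))),
      det_ord = ifelse(.data$detector == "pd", -Inf,
                       suppressWarnings(as.numeric(sub("^ch", "", .data$detector))))
    ) |>
    dplyr::arrange(.data$sample_id, .data$state_ord, .data$det_ord) |>
    dplyr::mutate(sample_id = as.character(.data$sample_id)) |>
    dplyr::select(-"state_ord", -"det_ord")
}

#' Write / read an instrument configuration as YAML
#'
#' All [instrument_spec()] fields round-trip, the crosstalk matrix as a
#' list of per-channel rows.
#'
#' @param instrument An [instrument_spec()].
#' @param path YAML file path.
#' @return `write_instrument()` returns `path` invisibly;
#'   `read_instrument()` returns an `instrument_spec`.
#' @export
write_instrument <- function(instrument, path) {
  stopifnot(inherits(instrument, "instrument_spec"))
  x <- unclass(instrument)
  ct <- x$crosstalk
  x$crosstalk <- stats::setNames(
    lapply(seq_len(nrow(ct)), function(i) as.numeric(ct[i, ])),
    rownames(ct))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_instrument
#' @export
read_instrument <- function(path) {
  x <- yaml::read_yaml(path)
  ct <- do.call(rbind, lapply(x$crosstalk, as.numeric))
  args <- x[setdiff(names(x), "crosstalk")]
  args$crosstalk <- ct
  do.call(instrument_spec, args)
}

#' Write a feature table (and optionally the ground truth) to CSV
#'
#' @param features Output of [assemble_features()].
#' @param path CSV path for the feature table.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()))
}
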