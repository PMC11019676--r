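#' MSE-versus-components curve
#'
#' @param object A [pls_loocv()] result.
#' @param ... Unused.
#' @return A ggplot: LOOCV mean squared error against component count,
#'   with the selected elbow marked.
#' @method autoplot pls_cv
#' @export
autoplot.pls_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ncomp, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::scale_x_continuous(breaks = df$ncomp) +
    ggplot2::labs(x = "PLS components", y = "LOOCV mean squared error") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-true concentrations
#'
#' @param object An `eem_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot faceted by fluorophore: LOOCV-predicted against true
#'   concentration with the identity line.
#' @method autoplot eem_report
#' @export
autoplot.eem_report <- function(object, ...) {
  df <- augment(object$cv) |>
    tidyr::pivot_longer(-dplyr::any_of("sample_id"),
                        names_to = "col", values_to = "value") |>
    dplyr::mutate(kind = ifelse(startsWith(.data$col, ".pred_"),
                                "predicted", "true"),
                  response = sub("^\\.pred_", "", .data$col)) |>
    dplyr::select(-"col") |>
    dplyr::group_by(.data$response, .data$kind) |>
    dplyr::mutate(row = dplyr::row_number()) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "value") |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~response, scales = "free") +
    ggplot2::labs(x = "true concentration (ug/ml)",
                  y = "LOOCV-predicted concentration (ug/ml)") +
    ggplot2::theme_minimal()
}

#' Crosstalk matrix heat map
#'
#' @param object A [crosstalk_matrix()] report.
#' @param ... Unused.
#' @return A ggplot tile map of log10 percentage leakage per
#'   (source, channel).
#' @method autoplot crosstalk_report
#' @export
autoplot.crosstalk_report <- function(object, ...) {
  df <- dplyr::mutate(object,
                      source = factor(.data$source),
                      channel = factor(.data$channel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$channel,
                                   fill = log10(.data$percent))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$percent, 2)),
                       size = 2.5) +
    ggplot2::scale_fill_viridis_c(name = "log10 %") +
    ggplot2::labs(x = "source (nm)", y = "channel (nm)") +
    ggplot2::theme_minimal()
}

#' Mean excitation-emission matrix of corrected frames
#'
#' @param corrected Output of [subtract_background()].
#' @return A ggplot tile map of the mean background-subtracted channel
#'   voltage per (source, channel) over all samples.
#' @export
plot_eem <- function(corrected) {
  df <- corrected |>
    dplyr::filter(grepl("^ch", .data$detector)) |>
    dplyr::mutate(source = factor(as.numeric(.data$state)),
                  channel = factor(as.numeric(sub("^ch", "", .data$detector)))) |>
    dplyr::group_by(.data$source, .data$channel) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$channel,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "V") +
    ggplot2::labs(x = "excitation source (nm)", y = "detection channel (nm)") +
    ggplot2::theme_minimal()
}
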