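#' Run the full phantom analysis chain
#'
#' End-to-end workflow: simulate raw frames for a phantom design (or take
#' frames already acquired), subtract the ambient background, assemble
#' the masked, reflectance-normalised feature matrix, cross-validate a
#' multi-response PLS model, select the component count by the MSE elbow
#' (or use a fixed count) and report per-fluorophore recovery.
#'
#' @param design Phantom design tibble (e.g. [factorial_design()]); used for
#'   simulation when `frames` is `NULL` and always as ground truth.
#' @param frames Optional pre-acquired raw frames; when `NULL`, frames
#'   are simulated from `design` with `seed`.
#' @param instrument,fluorophores,medium Forward-model configuration.
#' @param seed Global seed for the simulated acquisition.
#' @param normalization Passed to [assemble_features()].
#' @param components `"auto"` or a fixed component count.
#' @param ncomp_max,tau Passed to [pls_loocv()].
#' @param out_dir Optional directory; when given, writes `features.csv`,
#'   `predictions.csv` and `report.json` there.
#' @param verbose Log stage progress to `stderr`.
#' @return An object of class `"eem_report"`: the design, feature table,
#'   `pls_cv` result, selected component count, per-fluorophore
#'   R-squared, seed and a configuration hash.
#' @examples
#' \donttest{
#' rep <- run_pipeline(factorial_design(), seed = 1, components = 4)
#' rep$r2
#' }
#' @export
run_pipeline <- function(design,
                         frames = NULL,
                         instrument = instrument_spec(),
                         fluorophores = default_fluorophores(),
                         medium = optical_medium(),
                         seed = 1,
                         normalization = c("drs", "none"),
                         components = "auto",
                         ncomp_max = 8,
                         tau = 0.01,
                         out_dir = NULL,
                         verbose = FALSE) {
  normalization <- match.arg(normalization)
  say <- function(...) if (verbose) message("[eemphantom] ", ...)
  config_hash <- rlang::hash(list(instrument, fluorophores, medium, seed,
                                  normalization, components, ncomp_max, tau))
  if (is.null(frames)) {
    say("simulating ", nrow(design), " frames (seed ", seed, ")")
    frames <- simulate_frames(design, instrument, fluorophores, medium, seed)
  }
  say("subtracting ambient background")
  corrected <- subtract_background(frames, instrument)
  say("assembling feature matrix (", normalization, ")")
  features <- assemble_features(corrected, instrument, normalization)
  stopifnot(identical(features$sample_id, design$sample_id))

  responses <- design_responses(design)
  # constant concentration columns (e.g. the absent fluorophores of a
  # single-fluorophore series) are not learnable targets
  responses <- responses[vapply(design[responses],
                                function(v) dplyr::n_distinct(v) > 1,
                                logical(1))]
  if (!length(responses)) stop("design has no varying fluorophore", call. = FALSE)
  y <- as.matrix(design[responses])
  say("cross-validating PLS (ncomp_max ", ncomp_max, ")")
  cv <- pls_loocv(features, y, ncomp_max = ncomp_max,
                  components = components, tau = tau)
  say("selected k = ", cv$selected_k)

  report <- structure(
    list(design = design, features = features, cv = cv,
         selected_k = cv$selected_k, r2 = cv$r2,
         normalization = normalization, seed = seed,
         config_hash = config_hash),
    class = "eem_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_features(features, file.path(out_dir, "features.csv"))
    readr::write_csv(augment(cv), file.path(out_dir, "predictions.csv"))
    jsonlite::write_json(
      list(schema = "eemphantom-report/1",
           seed = seed, config_hash = config_hash,
           normalization = normalization,
           mse_per_k = cv$mse_per_k, selected_k = cv$selected_k,
           r2 = stats::setNames(as.list(cv$r2$r2), cv$r2$response)),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("wrote outputs to ", out_dir)
  }
  report
}

#' @export
print.eem_report <- function(x, ...) {
  cat("<eem_report> n = ", nrow(x$design), ", ", x$normalization,
      "-normalised, selected k = ", x$selected_k, "\n", sep = "")
  print(x$r2)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object An `eem_report`.
#' @param ... Unused.
#' @method glance eem_report
#' @export
glance.eem_report <- function(x, ...) {
  out <- tibble::tibble(n = nrow(x$design), selected_k = x$selected_k,
                        seed = x$seed)
  wide <- stats::setNames(as.list(x$r2$r2), paste0("r2_", x$r2$response))
  dplyr::bind_cols(out, tibble::as_tibble(wide))
}
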