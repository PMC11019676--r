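#' Coefficient of determination per response
#'
#' `1 - SSE/SST` computed column-wise, typically on leave-one-out
#' cross-validated predictions.
#'
#' @param y_true Observed responses (vector or n x q matrix/data frame).
#' @param y_pred Predictions of the same shape.
#' @return A named numeric vector, one value per response.
#' @examples
#' r_squared(1:4, c(1.1, 1.9, 3.2, 3.8))
#' @export
r_squared <- function(y_true, y_pred) {
  yt <- as_numeric_matrix(y_true, "y_true")
  yp <- as_numeric_matrix(y_pred, "y_pred")
  stopifnot(all(dim(yt) == dim(yp)), nrow(yt) >= 2)
  sst <- colSums(sweep(yt, 2, colMeans(yt))^2)
  if (any(sst == 0)) stop("response with zero variance", call. = FALSE)
  out <- 1 - colSums((yt - yp)^2) / sst
  names(out) <- colnames(yt) %||% paste0("y", seq_len(ncol(yt)))
  out
}

#' Elbow rule for the number of PLS components
#'
#' Scans the LOOCV mean-squared-error curve and returns the smallest k
#' whose improvement to k+1, relative to the one-component error, falls
#' below `tau`: the point after which the MSE no longer changes
#' appreciably. Returns the largest k in the curve if the improvements
#' never flatten out.
#'
#' @param mse_per_k Numeric MSE values for k = 1, 2, ... components.
#' @param tau Relative-improvement threshold (default 0.01, i.e. 1 % of
#'   the one-component MSE).
#' @return The selected number of components (integer).
#' @examples
#' select_components(c(1, 0.4, 0.2, 0.1, 0.099, 0.098))  # 4
#' @export
select_components <- function(mse_per_k, tau = 0.01) {
  stopifnot(length(mse_per_k) >= 1, tau > 0, all(is.finite(mse_per_k)))
  k_max <- length(mse_per_k)
  if (k_max == 1) return(1L)
  rel_gain <- (mse_per_k[-k_max] - mse_per_k[-1]) / mse_per_k[1]
  flat <- which(rel_gain < tau)
  if (length(flat)) flat[1] else k_max
}

#' Leave-one-out cross-validated PLS
#'
#' Refits the PLS model n times, each time excluding one sample and
#' predicting it, and records the cross-validated predictions for every
#' component count up to `ncomp_max`. The MSE curve (mean over rows and
#' responses, responses on their natural concentration scales) drives the
#' elbow rule of [select_components()] unless a fixed component count is
#' requested; per-response R-squared is computed on the cross-validated
#' predictions at the selected k.
#'
#' @inheritParams fit_pls
#' @param ncomp_max Largest component count to evaluate (capped at
#'   `min(n - 2, p)` so every leave-one-out fit is defined).
#' @param components `"auto"` to select by the elbow rule, or a fixed
#'   integer component count.
#' @param tau Elbow threshold passed to [select_components()].
#' @return An object of class `"pls_cv"`: `predictions` (n x q, at the
#'   selected k), `pred_by_k` (n x q x ncomp_max array), `mse_per_k`,
#'   `selected_k`, `r2` (tibble `response`, `r2`), `y` (the observed
#'   responses) and `row_ids`.
#' @export
pls_loocv <- function(x, y, ncomp_max = 8, components = "auto", tau = 0.01,
                      scale = FALSE) {
  row_ids <- if (is.data.frame(x) && "sample_id" %in% names(x)) x$sample_id else NULL
  if (is.data.frame(x) && "sample_id" %in% names(x)) {
    x <- dplyr::select(x, -"sample_id")
  }
  x <- as_numeric_matrix(x, "x")
  y <- as_numeric_matrix(y, "y")
  n <- nrow(x); q <- ncol(y)
  stopifnot(nrow(y) == n, n >= 3)
  keep <- stats::complete.cases(x) & stats::complete.cases(y)
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) with missing features excluded from ",
            "cross-validation", call. = FALSE)
    x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
    if (!is.null(row_ids)) row_ids <- row_ids[keep]
    n <- nrow(x)
  }
  ncomp_max <- min(ncomp_max, n - 2, ncol(x))
  if (!identical(components, "auto")) {
    components <- as.integer(components)
    stopifnot(components >= 1)
    ncomp_max <- max(ncomp_max, components)
  }

  pred <- array(NA_real_, dim = c(n, q, ncomp_max),
                dimnames = list(NULL, colnames(y) %||% paste0("y", seq_len(q)),
                                NULL))
  for (i in seq_len(n)) {
    fit <- fit_pls(x[-i, , drop = FALSE], y[-i, , drop = FALSE],
                   ncomp = ncomp_max, scale = scale)
    for (k in seq_len(ncomp_max)) {
      pred[i, , k] <- predict(fit, x[i, , drop = FALSE], ncomp = k)
    }
  }

  mse_per_k <- vapply(seq_len(ncomp_max), function(k) {
    mean((pred[, , k] - y)^2)
  }, numeric(1))
  selected_k <- if (identical(components, "auto")) {
    as.integer(select_components(mse_per_k, tau))
  } else {
    as.integer(min(components, ncomp_max))
  }
  colnames(y) <- dimnames(pred)[[2]]
  predictions <- pred[, , selected_k, drop = TRUE]
  if (q == 1) predictions <- matrix(predictions, ncol = 1)
  colnames(predictions) <- dimnames(pred)[[2]]
  structure(
    list(predictions = predictions, pred_by_k = pred,
         mse_per_k = mse_per_k, selected_k = selected_k, tau = tau,
         r2 = tibble::tibble(response = dimnames(pred)[[2]],
                             r2 = unname(r_squared(y, predictions))),
         y = y, row_ids = row_ids),
    class = "pls_cv"
  )
}

#' @export
print.pls_cv <- function(x, ...) {
  cat("<pls_cv> n = ", nrow(x$y), ", selected k = ", x$selected_k, "\n",
      sep = "")
  print(x$r2)
  invisible(x)
}

#' @rdname pls_loocv
#' @param x,object A `pls_cv` object.
#' @param ... Unused.
#' @method tidy pls_cv
#' @export
tidy.pls_cv <- function(x, ...) {
  tibble::tibble(ncomp = seq_along(x$mse_per_k), mse = x$mse_per_k,
                 selected = seq_along(x$mse_per_k) == x$selected_k)
}

#' @rdname pls_loocv
#' @method glance pls_cv
#' @export
glance.pls_cv <- function(x, ...) {
  tibble::tibble(n = nrow(x$y), q = ncol(x$y),
                 ncomp_max = length(x$mse_per_k),
                 selected_k = x$selected_k,
                 mse = x$mse_per_k[x$selected_k])
}

#' @rdname pls_loocv
#' @method augment pls_cv
#' @export
augment.pls_cv <- function(x, ...) {
  obs <- tibble::as_tibble(x$y)
  prd <- tibble::as_tibble(x$predictions)
  names(prd) <- paste0(".pred_", names(prd))
  out <- dplyr::bind_cols(obs, prd)
  if (!is.null(x$row_ids)) out <- dplyr::bind_cols(
    tibble::tibble(sample_id = x$row_ids), out)
  out
}
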