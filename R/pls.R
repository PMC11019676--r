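as_numeric_matrix <- function(x, what = "x") {
  if (is.data.frame(x)) {
    x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  }
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  x
}

#' Multi-response partial least squares (NIPALS PLS2)
#'
#' Fits a PLS2 regression of `y` (one column per response, e.g. the three
#' fluorophore concentrations) on `x` (the normalised feature matrix) by
#' the NIPALS algorithm on mean-centered data. Components are extracted
#' sequentially with deflation, so a fitted model contains every nested
#' sub-model with fewer components. Centering only by default: after
#' reflectance normalisation all features share a common scale, so
#' unit-variance scaling is optional.
#'
#' @param x Predictors: numeric matrix or data frame, n x p, no missing
#'   values (a `sample_id` column is ignored if present).
#' @param y Responses: numeric matrix, data frame or vector, n x q.
#' @param ncomp Number of latent components, `1 <= ncomp <= min(n-1, p)`.
#' @param scale Logical; also scale predictor columns to unit variance.
#' @param tol,max_iter NIPALS convergence tolerance on the score vector
#'   and iteration cap per component.
#' @return An object of class `"pls_fit"` with elements `weights` (p x k),
#'   `x_loadings` (p x k), `y_loadings` (q x k), `scores` (n x k),
#'   `x_mean`, `y_mean`, `coef` (p x q, at the full `ncomp`), `ncomp`,
#'   and `ncomp_used` (smaller than `ncomp` only when the residual matrix
#'   ran out of variance early).
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' y <- x %*% c(1, -1, 0.5) + rnorm(20, sd = 0.01)
#' fit <- fit_pls(x, y, ncomp = 3)
#' glance(fit)
#' @export
fit_pls <- function(x, y, ncomp, scale = FALSE, tol = 1e-10, max_iter = 500) {
  if (is.data.frame(x) && "sample_id" %in% names(x)) {
    x <- dplyr::select(x, -"sample_id")
  }
  x <- as_numeric_matrix(x, "x")
  y <- as_numeric_matrix(y, "y")
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  stopifnot(nrow(y) == n)
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y", call. = FALSE)
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    stop("ncomp must lie in [1, min(n-1, p)]", call. = FALSE)
  }

  x_mean <- colMeans(x)
  y_mean <- colMeans(y)
  xc <- sweep(x, 2, x_mean)
  yc <- sweep(y, 2, y_mean)
  x_sd <- NULL
  if (scale) {
    x_sd <- apply(xc, 2, stats::sd)
    x_sd[x_sd == 0] <- 1
    xc <- sweep(xc, 2, x_sd, "/")
  }

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); Tt <- matrix(0, n, ncomp)
  eps <- .Machine$double.eps
  k_used <- 0L
  for (a in seq_len(ncomp)) {
    if (sum(yc^2) < eps * n * q || sum(xc^2) < eps * n * p) break
    # deterministic start: the residual response column with most variance
    u <- yc[, which.max(colSums(yc^2))]
    t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(xc, u)[, 1]
      w <- w / sqrt(sum(w^2))
      tt <- xc %*% w
      qv <- crossprod(yc, tt)[, 1] / sum(tt^2)
      if (q > 1) u <- (yc %*% qv) / sum(qv^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2)) || q == 1) break
      if (it == max_iter) {
        stop("NIPALS failed to converge in ", max_iter, " iterations",
             call. = FALSE)
      }
      t_old <- tt
    }
    pv <- crossprod(xc, tt)[, 1] / sum(tt^2)
    xc <- xc - tt %*% t(pv)
    yc <- yc - tt %*% t(qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tt[, a] <- tt
    k_used <- a
  }

  coef <- pls_coef(W, P, Q, k_used, p, q)
  if (scale) coef <- coef / x_sd
  structure(
    list(weights = W, x_loadings = P, y_loadings = Q, scores = Tt,
         x_mean = x_mean, y_mean = y_mean, x_sd = x_sd,
         coef = coef, ncomp = ncomp, ncomp_used = k_used,
         x_names = colnames(x) %||% paste0("x", seq_len(p)),
         y_names = colnames(y) %||% paste0("y", seq_len(q))),
    class = "pls_fit"
  )
}

# regression coefficients from the first k components: B = W (P'W)^-1 Q'
pls_coef <- function(W, P, Q, k, p, q) {
  if (k == 0) return(matrix(0, p, q))
  Wk <- W[, seq_len(k), drop = FALSE]
  Pk <- P[, seq_len(k), drop = FALSE]
  Qk <- Q[, seq_len(k), drop = FALSE]
  Wk %*% solve(crossprod(Pk, Wk), t(Qk))
}

#' Predict responses from a fitted PLS model
#'
#' @param object A [fit_pls()] model.
#' @param newdata Predictor matrix or data frame with the model's p
#'   columns (a `sample_id` column is ignored).
#' @param ncomp Number of components to use, up to the fitted number;
#'   defaults to the full model.
#' @param ... Unused.
#' @return An n x q matrix of predicted responses.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = NULL, ...) {
  if (is.data.frame(newdata) && "sample_id" %in% names(newdata)) {
    newdata <- dplyr::select(newdata, -"sample_id")
  }
  x <- as_numeric_matrix(newdata, "newdata")
  if (ncol(x) != length(object$x_mean)) {
    stop("newdata has ", ncol(x), " columns; model expects ",
         length(object$x_mean), call. = FALSE)
  }
  k <- if (is.null(ncomp)) object$ncomp_used else min(ncomp, object$ncomp_used)
  B <- pls_coef(object$weights, object$x_loadings, object$y_loadings,
                k, length(object$x_mean), length(object$y_mean))
  if (!is.null(object$x_sd)) B <- B / object$x_sd
  out <- sweep(x, 2, object$x_mean) %*% B
  out <- sweep(out, 2, object$y_mean, "+")
  colnames(out) <- object$y_names
  out
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("<pls_fit> ", x$ncomp_used, " component(s), p = ",
      length(x$x_mean), ", q = ", length(x$y_mean), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_pls
#' @param x,object A `pls_fit` object.
#' @param ... Unused.
#' @method tidy pls_fit
#' @export
tidy.pls_fit <- function(x, ...) {
  tibble::tibble(
    term = rep(x$x_names, times = length(x$y_names)),
    response = rep(x$y_names, each = length(x$x_names)),
    estimate = as.vector(x$coef)
  )
}

#' @rdname fit_pls
#' @method glance pls_fit
#' @export
glance.pls_fit <- function(x, ...) {
  tibble::tibble(
    ncomp = x$ncomp, ncomp_used = x$ncomp_used,
    n = nrow(x$scores), p = length(x$x_mean), q = length(x$y_mean)
  )
}
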