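test_that("PLS at full rank reproduces ordinary least squares", {
  set.seed(101)
  for (rep in 1:3) {
    n <- 15 + rep; p <- 4
    x <- matrix(rnorm(n * p), n, p)
    y <- cbind(x %*% rnorm(p) + rnorm(n, sd = 0.3),
               x %*% rnorm(p) + rnorm(n, sd = 0.3))
    fit <- fit_pls(x, y, ncomp = p)
    ols <- cbind(fitted(lm(y[, 1] ~ x)), fitted(lm(y[, 2] ~ x)))
    expect_equal(unname(predict(fit, x)), unname(ols), tolerance = 1e-8)
    # training residuals match the OLS residuals too
    expect_equal(unname(y - predict(fit, x)),
                 unname(cbind(resid(lm(y[, 1] ~ x)), resid(lm(y[, 2] ~ x)))),
                 tolerance = 1e-8)
  }
})

test_that("univariate single-predictor PLS recovers the regression slope", {
  set.seed(7)
  x <- rnorm(30)
  y <- 2.5 * x + rnorm(30, sd = 0.1)
  fit <- fit_pls(x, y, ncomp = 1)
  # closed-form simple-regression slope
  expect_equal(as.numeric(fit$coef), cov(x, y) / var(x), tolerance = 1e-10)
  expect_equal(as.numeric(fit$coef), coef(lm(y ~ x))[["x"]], tolerance = 1e-10)
})

test_that("constant responses give zero coefficients and mean predictions", {
  set.seed(8)
  x <- matrix(rnorm(40), 10, 4)
  y <- matrix(3, 10, 1)
  fit <- fit_pls(x, y, ncomp = 2)
  expect_equal(unname(fit$coef), matrix(0, 4, 1))
  expect_equal(unname(predict(fit, x)), matrix(3, 10, 1))
})

test_that("predicting at the training mean returns the response mean", {
  set.seed(9)
  x <- matrix(rnorm(60), 20, 3)
  y <- x %*% rnorm(3) + rnorm(20, sd = 0.2)
  fit <- fit_pls(x, y, ncomp = 2)
  expect_equal(as.numeric(predict(fit, matrix(fit$x_mean, 1))),
               as.numeric(fit$y_mean))
})

test_that("successive score vectors are orthogonal", {
  set.seed(10)
  x <- matrix(rnorm(200), 25, 8)
  y <- cbind(x %*% rnorm(8), x %*% rnorm(8)) + rnorm(25)
  fit <- fit_pls(x, y, ncomp = 5)
  g <- crossprod(fit$scores)
  off <- g - diag(diag(g))
  expect_lt(max(abs(off)) / max(diag(g)), 1e-8)
})

test_that("PLS agrees with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(11)
  x <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- cbind(a = x %*% rnorm(6) + rnorm(30, sd = 0.2),
             b = x %*% rnorm(6) + rnorm(30, sd = 0.2))
  fit <- fit_pls(x, y, ncomp = 4)
  ref <- mixOmics::pls(x, y, ncomp = 4, scale = FALSE, mode = "regression")
  ref_pred <- predict(ref, x)$predict
  for (k in 1:4) {
    expect_equal(unname(predict(fit, x, ncomp = k)), unname(ref_pred[, , k]),
                 tolerance = 1e-6)
  }
})

test_that("parameter errors are caught", {
  x <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  expect_error(fit_pls(x, y, ncomp = 3), "ncomp")
  expect_error(fit_pls(x, c(y[-1], NA), ncomp = 1), "missing")
  fit <- fit_pls(x, y, ncomp = 2)
  expect_error(predict(fit, matrix(1, 2, 3)), "columns")
})

test_that("LOOCV predicts each row from a model that never saw it", {
  set.seed(12)
  x <- matrix(rnorm(20 * 4), 20, 4)
  y <- x %*% rnorm(4) + rnorm(20, sd = 0.3)
  cv <- pls_loocv(x, y, ncomp_max = 3, components = 2)
  # corrupting row i's response must not move row i's prediction:
  # only the other rows' models see it
  i <- 5
  y2 <- y; y2[i] <- 1e6
  cv2 <- pls_loocv(x, y2, ncomp_max = 3, components = 2)
  expect_equal(cv2$predictions[i, ], cv$predictions[i, ])
  expect_false(isTRUE(all.equal(cv2$predictions[-i, ], cv$predictions[-i, ])))
})

test_that("LOOCV matches a brute-force fit/predict loop", {
  set.seed(13)
  x <- matrix(rnorm(12 * 3), 12, 3)
  y <- cbind(x %*% rnorm(3) + rnorm(12, sd = 0.2),
             x %*% rnorm(3) + rnorm(12, sd = 0.2))
  cv <- pls_loocv(x, y, ncomp_max = 2)
  for (k in 1:2) {
    brute <- matrix(NA_real_, 12, 2)
    for (i in 1:12) {
      f <- fit_pls(x[-i, ], y[-i, ], ncomp = k)
      brute[i, ] <- predict(f, x[i, , drop = FALSE])
    }
    expect_equal(mean((brute - y)^2), cv$mse_per_k[k])
  }
})

test_that("LOOCV handles structure and degenerate learnable cases", {
  # minimal n = 3 case
  x <- matrix(c(1, 2, 3, 2, 1, 3), 3, 2)
  y <- c(1, 2, 3)
  cv <- pls_loocv(x, y, ncomp_max = 5)
  expect_equal(nrow(cv$predictions), 3)
  expect_equal(length(cv$mse_per_k), 1)  # capped at n - 2
  # duplicated rows with exactly linear response: near-zero LOOCV error
  set.seed(14)
  xb <- matrix(rnorm(15), 5, 3)
  xd <- rbind(xb, xb, xb)
  yd <- xd %*% c(1, -2, 0.5)
  cvd <- pls_loocv(xd, yd, ncomp_max = 3, components = 3)
  expect_lt(cvd$mse_per_k[3], 1e-20)
})

test_that("the elbow rule selects the first flat improvement", {
  expect_equal(select_components(c(1.0, 0.4, 0.2, 0.1, 0.099, 0.098),
                                 tau = 0.01), 4)
  expect_equal(select_components(rep(0.5, 6), tau = 0.01), 1)
  expect_equal(select_components(c(1, 0.5, 0.25, 0.12), tau = 0.01), 4)
  expect_equal(select_components(0.3), 1)
  # monotone in tau: a larger threshold never selects more components
  set.seed(15)
  for (rep in 1:20) {
    curve <- rev(sort(runif(8)))
    taus <- c(0.001, 0.01, 0.05, 0.2, 0.5)
    ks <- vapply(taus, function(t) select_components(curve, t), numeric(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("r_squared matches its definition", {
  expect_equal(unname(r_squared(1:5, 1:5)), 1)
  y <- c(2, 4, 6, 8)
  expect_equal(unname(r_squared(y, rep(mean(y), 4))), 0)
  # hand-worked 4-point example: SSE = 0.10, SST = 5
  expect_equal(unname(r_squared(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))), 0.98)
  expect_error(r_squared(rep(1, 4), rnorm(4)), "zero variance")
})

test_that("tidy, glance and augment return well-formed tibbles", {
  set.seed(16)
  x <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- cbind(a = as.numeric(x %*% rnorm(3)) + rnorm(15, 0.1))
  fit <- fit_pls(x, y, ncomp = 2)
  td <- tidy(fit)
  expect_equal(names(td), c("term", "response", "estimate"))
  expect_equal(nrow(td), 3)
  expect_equal(glance(fit)$p, 3)
  cv <- pls_loocv(x, y, ncomp_max = 3)
  expect_equal(names(tidy(cv)), c("ncomp", "mse", "selected"))
  aug <- augment(cv)
  expect_true(all(c("a", ".pred_a") %in% names(aug)))
})
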