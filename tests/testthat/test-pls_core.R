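test_that("autoscale centers and scales, and flags constant columns", {
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a"))
  out <- autoscale(m)
  expect_equal(drop(out$values), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(out$center, c(a = 2))
  expect_equal(out$scale, c(a = 1))

  const <- cbind(m, b = c(5, 5, 5))
  expect_warning(out2 <- autoscale(const), "zero-variance")
  expect_equal(drop(out2$values[, "b"]), c(0, 0, 0))

  big <- random_labelled_matrix(50, 8, seed = 4)
  sc <- autoscale(big)$values
  expect_true(all(abs(colMeans(sc)) < 1e-12))
  expect_true(all(abs(apply(sc, 2, stats::var) - 1) < 1e-12))
  expect_error(autoscale(matrix(numeric(0), 0, 0)), "empty")
})

test_that("univariate NIPALS is a single pass with unit response loading", {
  X <- random_labelled_matrix(30, 5, seed = 8)
  set.seed(9)
  y <- matrix(rnorm(30), 30, 1)
  comp <- nipals_component(autoscale(X)$values, y)
  expect_identical(comp$iterations, 0L)
  expect_identical(comp$q, 1)
  # after rescaling the X-loading has unit length
  expect_equal(sqrt(sum(comp$p^2)), 1, tolerance = 1e-12)
  # duplicating the response column forces the iterative path; its scores must
  # agree with the single-pass ones
  comp2 <- nipals_component(autoscale(X)$values, cbind(y, y))
  expect_gt(comp2$iterations, 0L)
  expect_equal(comp2$t, comp$t, tolerance = 1e-12)
  expect_equal(comp2$w, comp$w, tolerance = 1e-12)
})

test_that("a response proportional to one predictor is recovered exactly", {
  # orthonormal centered predictors make the single-component fixed point
  # analytic: w = e2, t = X e2, b = the proportionality constant
  set.seed(10)
  Xs <- qr.Q(qr(scale(matrix(rnorm(25 * 4), 25, 4), scale = FALSE)))
  y <- Xs[, 2, drop = FALSE] * 3
  comp <- nipals_component(Xs, y)
  expect_gt(abs(stats::cor(comp$t, Xs[, 2])), 1 - 1e-10)
  # the rank-one model reproduces y: b * t * q = y
  expect_equal(comp$b * comp$t, drop(y), tolerance = 1e-8)
  expect_equal(comp$b, 3, tolerance = 1e-8)
})

test_that("the first component matches the dominant singular direction", {
  X <- random_labelled_matrix(30, 5, seed = 12)
  Y <- random_labelled_matrix(30, 2, seed = 13, prefix = "y")
  Xs <- autoscale(X)$values
  Yc <- scale(Y, scale = FALSE)
  comp <- nipals_component(Xs, Yc)
  sv <- svd(crossprod(Xs, Yc))
  t_svd <- drop(Xs %*% sv$u[, 1])
  expect_gt(abs(stats::cor(comp$t, t_svd)), 1 - 1e-6)
})

test_that("full-component PLS coincides with ordinary least squares", {
  X <- random_labelled_matrix(40, 6, seed = 14)
  Y <- random_labelled_matrix(40, 3, seed = 15, prefix = "y")
  model <- fit_pls(X, Y, n_components = 6)
  pred <- pls_predict(model, X)
  ols <- vapply(seq_len(ncol(Y)), function(j) {
    stats::lm.fit(cbind(1, X), Y[, j])$fitted.values
  }, numeric(nrow(X)))
  expect_lt(max(abs(pred - ols)), 1e-6)
})

test_that("scores are mutually orthogonal and explained variance grows", {
  X <- random_labelled_matrix(40, 6, seed = 16)
  Y <- random_labelled_matrix(40, 3, seed = 17, prefix = "y")
  model <- fit_pls(X, Y, n_components = 6)
  Tm <- vapply(model$components, `[[`, numeric(40), "t")
  G <- crossprod(Tm)
  nrm <- sqrt(diag(G))
  cosines <- abs(G / outer(nrm, nrm))[upper.tri(G)]
  expect_true(all(cosines < 1e-8))
  expect_true(all(diff(model$cum_var_y_pct) >= -1e-10))
  expect_true(all(diff(model$cum_var_x_pct) >= -1e-10))
})

test_that("a noiseless linear system is explained completely", {
  X <- random_labelled_matrix(30, 5, seed = 18)
  set.seed(19)
  C <- matrix(rnorm(15), 3, 5)
  Y <- X %*% t(C)
  colnames(Y) <- paste0("y", 1:3)
  model <- fit_pls(X, Y, n_components = 5)
  expect_equal(utils::tail(model$cum_var_y_pct, 1), 100, tolerance = 1e-6)
  # held-out rows from the same noiseless system are recovered
  X_new <- random_labelled_matrix(10, 5, seed = 20)
  expect_lt(max(abs(pls_predict(model, X_new) - X_new %*% t(C))), 1e-6)
})

test_that("component-count and column-name violations are errors", {
  X <- random_labelled_matrix(20, 4, seed = 21)
  Y <- random_labelled_matrix(20, 2, seed = 22, prefix = "y")
  expect_error(fit_pls(X, Y, n_components = 0), "positive")
  expect_error(fit_pls(X, Y, n_components = 5), "rank")
  model <- fit_pls(X, Y, n_components = 2)
  X_bad <- X
  colnames(X_bad)[1] <- "other"
  expect_error(pls_predict(model, X_bad), "missing.*v01|other")
})

test_that("prediction on the training block reproduces fitted values", {
  X <- random_labelled_matrix(25, 5, seed = 23)
  Y <- random_labelled_matrix(25, 2, seed = 24, prefix = "y")
  model <- fit_pls(X, Y, n_components = 3)
  # reconstruct fitted values from the stored decomposition
  Yc <- sweep(Y, 2, model$y_center, "-")
  fitted <- Reduce(`+`, lapply(model$components, function(cp) {
    cp$b * tcrossprod(cp$t, cp$q)
  }))
  expect_equal(unname(pls_predict(model, X)),
               unname(sweep(fitted, 2, model$y_center, "+")),
               tolerance = 1e-10)
  one_row <- pls_predict(model, X[3, , drop = FALSE])
  expect_equal(one_row, pls_predict(model, X)[3, , drop = FALSE],
               tolerance = 1e-12)
})

test_that("explained variance follows its defining formula", {
  Y <- random_labelled_matrix(10, 3, seed = 25)
  expect_equal(explained_variance_pct(Y, Y), 100)
  expect_equal(explained_variance_pct(Y, Y * 0), 0)
  expect_equal(explained_variance_pct(Y, Y / 2), 75)
  expect_lt(explained_variance_pct(Y, -Y), 0)
  expect_error(explained_variance_pct(Y * 0, Y), "zero")
})

test_that("the PLS core agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  X <- random_labelled_matrix(30, 6, seed = 26)
  set.seed(27)
  y <- drop(X %*% rnorm(6)) + rnorm(30, sd = 0.5)
  ours <- fit_pls(X, matrix(y, dimnames = list(rownames(X), "y")),
                  n_components = 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, scale = TRUE, mode = "regression")
  pred_ref <- predict(ref, X)$predict[, 1, 3]
  # univariate responses make both parameterizations identical
  expect_equal(unname(drop(pls_predict(ours, X))), unname(pred_ref),
               tolerance = 1e-6)
})
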