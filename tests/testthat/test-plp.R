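test_that("projection recovers weighting factors of rank-one flux data", {
  set.seed(30)
  em <- rnorm(6)
  em <- em / sqrt(sum(em^2))
  lambda_star <- rnorm(15)
  R <- tcrossprod(lambda_star, em)
  expect_equal(project_lambda(R, em), lambda_star, tolerance = 1e-12)
  # orthogonal mode projects to zero
  em_perp <- rnorm(6)
  em_perp <- em_perp - sum(em_perp * em) * em
  expect_lt(max(abs(project_lambda(R, em_perp))), 1e-10)
  # row-wise dot products recomputed independently
  R2 <- matrix(rnorm(60), 10, 6)
  v <- rnorm(6)
  lam <- project_lambda(R2, v, normalization = "raw")
  for (i in 1:10) expect_equal(lam[i], sum(R2[i, ] * v))
  expect_error(project_lambda(R2, rep(0, 6)), "nonzero")
})

test_that("named projections align by flux name and catch mismatches", {
  R <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  em <- stats::setNames(c(1, 0, 2, 0), paste0("f", c(3, 2, 1, 4)))
  lam <- project_lambda(R, em, normalization = "raw")
  expect_equal(lam, drop(R %*% c(2, 0, 1, 0)))
  names(em) <- paste0("g", 1:4)
  expect_error(project_lambda(R, em), "mismatch")
})

test_that("a noiselessly predictable weighting factor scores near-perfectly", {
  X <- random_labelled_matrix(40, 6, seed = 31)
  Xs <- autoscale(X)$values
  lambda <- drop(Xs[, 1] * 2 + Xs[, 2] * -1)
  em <- c(1, 0, 0)
  R <- tcrossprod(lambda, em)
  # at full rank the inner PLS equals least squares, so the noiseless linear
  # target is reproduced exactly
  sc <- evaluate_candidate(Xs, R, em, plp_config(n_inner_latent = 6))
  expect_gt(sc$r2, 1 - 1e-8)
  expect_lt(sc$p_value, 1e-10)
  expect_equal(sc$var_R_pct, 100, tolerance = 1e-6)
  expect_equal(sc$var_lambda_pct, 100, tolerance = 1e-6)
  # a few latent variables already capture it to high accuracy
  sc2 <- evaluate_candidate(Xs, R, em, plp_config(n_inner_latent = 2))
  expect_gt(sc2$r2, 0.99)
})

test_that("a zero-variance weighting factor is flagged, not an error", {
  X <- random_labelled_matrix(20, 4, seed = 32)
  Xs <- autoscale(X)$values
  R <- matrix(rnorm(60), 20, 3)
  em <- c(0, 0, 0)
  sc <- evaluate_candidate(Xs, R, em, plp_config())
  expect_true(sc$degenerate)
  expect_equal(sc$r2, 0)
  expect_equal(sc$p_value, 1)
})

test_that("null candidates overfit the inner model but rarely cross the gate", {
  # with Fac latent variables over nx predictors the inner PLS overfits toward
  # the OLS level nx/np, far above Fac/np; the r2 threshold is the operative
  # false-selection control
  set.seed(33)
  np <- 67
  X <- matrix(rnorm(np * 26), np, 26)
  Xs <- autoscale(X)$values
  cfg <- plp_config()
  r2s <- vapply(1:400, function(i) {
    lam <- rnorm(np)
    evaluate_candidate(Xs, matrix(lam, np, 1), 1, cfg)$r2
  }, numeric(1))
  expect_gt(mean(r2s), cfg$n_inner_latent / np)
  expect_lt(mean(r2s), 26 / (np - 1) + 0.15)
  expect_lt(mean(r2s > cfg$r2_threshold), 0.005)
})

test_that("the selection loop recovers the planted active set first", {
  bm <- make_benchmark(seed = 41)
  model <- select_efms(bm$ds$X, bm$ds$R, bm$lib, plp_config())
  expect_setequal(model$selected_ids[1:3], 1:3)
  expect_true(all(diff(model$cum_var_R_pct) >= 0))
  expect_false(any(duplicated(model$selected_ids)))
  # diagnostics of every accepted mode clear the thresholds
  tab <- selection_table(model)
  expect_true(all(tab$r2 > 0.75))
  expect_true(all(tab$p_value < 0.05))
})

test_that("greedy dominance: each accepted mode maximised residual variance", {
  bm <- make_benchmark(seed = 42)
  cfg <- plp_config()
  model <- select_efms(bm$ds$X, bm$ds$R, bm$lib, cfg)
  # replay the loop and re-score every remaining candidate at each iteration
  Xs <- autoscale(bm$ds$X)$values
  Rw <- sweep(bm$ds$R, 2, colMeans(bm$ds$R), "-")
  V <- bm$lib$EM[match(colnames(bm$ds$R), bm$lib$reaction_ids), ]
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  remaining <- bm$lib$efm_ids
  for (sel in model$selected) {
    vars <- vapply(remaining, function(id) {
      evaluate_candidate(Xs, Rw, V[, id], cfg)$var_R_pct
    }, numeric(1))
    expect_equal(sel$efm_id, remaining[which.max(vars)])
    expect_gte(sel$score$var_R_pct + 1e-9, max(vars))
    # re-evaluating the accepted mode on the deflated residual explains ~nothing
    Rw <- Rw - tcrossprod(sel$lambda_hat, V[, sel$efm_id])
    re_sc <- evaluate_candidate(Xs, Rw, V[, sel$efm_id], cfg)
    expect_lt(re_sc$var_R_pct, 5)
    remaining <- setdiff(remaining, sel$efm_id)
  }
})

test_that("pure-noise enviromes select nothing under default thresholds", {
  bm <- make_benchmark(seed = 43)
  Xn <- random_labelled_matrix(nrow(bm$ds$X), ncol(bm$ds$X), seed = 44,
                               prefix = "env_")
  colnames(Xn) <- colnames(bm$ds$X)
  rownames(Xn) <- rownames(bm$ds$X)
  model <- select_efms(Xn, bm$ds$R, bm$lib, plp_config())
  expect_length(model$selected_ids, 0L)
  expect_match(model$stop_reason, "gate")
})

test_that("max_efms caps selection at the single best candidate", {
  bm <- make_benchmark(seed = 45)
  model <- select_efms(bm$ds$X, bm$ds$R, bm$lib, plp_config(max_efms = 1))
  expect_length(model$selected_ids, 1L)
  expect_true(model$selected_ids %in% 1:3)
})

test_that("fitted PLP predictions reproduce the calibration variance exactly", {
  bm <- make_benchmark(seed = 46)
  model <- select_efms(bm$ds$X, bm$ds$R, bm$lib, plp_config())
  Rc <- sweep(bm$ds$R, 2, model$r_center, "-")
  Rhat_c <- sweep(plp_predict(model, bm$ds$X), 2, model$r_center, "-")
  expect_equal(explained_variance_pct(Rc, Rhat_c),
               utils::tail(model$cum_var_R_pct, 1), tolerance = 1e-9)
  # residual block equals data minus prediction
  expect_equal(unname(model$residual_R), unname(Rc - Rhat_c), tolerance = 1e-9)
})

test_that("noiseless validation rows predict almost as well as calibration", {
  lib <- generate_efm_library(n_efm = 60, n_disjoint = 3, seed = 47)
  ds <- generate_dataset(lib, generator_spec(
    n_obs = 160, active_efm_ids = 1:3, noise_sd_R = 0, noise_sd_X = 0, seed = 47))
  # interleaved split keeps validation points inside every experiment's range
  cal <- seq(1, 160, by = 2)
  val <- seq(2, 160, by = 2)
  model <- select_efms(ds$X[cal, ], ds$R[cal, ], lib, plp_config())
  Rv_c <- sweep(ds$R[val, ], 2, model$r_center, "-")
  val_var <- explained_variance_pct(
    Rv_c, sweep(plp_predict(model, ds$X[val, ]), 2, model$r_center, "-"))
  expect_gt(val_var, utils::tail(model$cum_var_R_pct, 1) - 2)
})

test_that("a model with nothing selected predicts the column-mean baseline", {
  bm <- make_benchmark(seed = 48)
  Xn <- random_labelled_matrix(nrow(bm$ds$X), ncol(bm$ds$X), seed = 49,
                               prefix = "e")
  colnames(Xn) <- colnames(bm$ds$X)
  rownames(Xn) <- rownames(bm$ds$X)
  model <- select_efms(Xn, bm$ds$R, bm$lib, plp_config())
  pred <- plp_predict(model, Xn[1:5, ])
  expect_equal(unname(pred),
               matrix(rep(colMeans(bm$ds$R), each = 5), 5),
               tolerance = 1e-12)
})

test_that("interface misuse is caught with informative errors", {
  bm <- make_benchmark(seed = 50)
  X2 <- bm$ds$X
  rownames(X2)[3] <- "intruder"
  expect_error(select_efms(X2, bm$ds$R, bm$lib, plp_config()),
               "intruder")
  R2 <- bm$ds$R
  colnames(R2)[1] <- "unknown_flux"
  expect_error(select_efms(bm$ds$X, R2, bm$lib, plp_config()),
               "unknown_flux")
  model <- select_efms(bm$ds$X, bm$ds$R, bm$lib, plp_config())
  Xbad <- bm$ds$X[, -1]
  expect_error(plp_predict(model, Xbad), "missing")
})

test_that("negative weighting factors are reported as a diagnostic", {
  bm <- make_benchmark(seed = 51)
  model <- select_efms(bm$ds$X, bm$ds$R, bm$lib, plp_config())
  fr <- vapply(model$selected, function(s) s$score$neg_lambda_frac, numeric(1))
  expect_true(all(fr >= 0 & fr <= 1))
})
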