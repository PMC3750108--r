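#' Autoscale the columns of a data matrix
#'
#' Centers every column to mean zero and scales it to unit variance (the
#' standard chemometric preprocessing of an envirome block). Columns with
#' zero variance are centered only (scale fixed at 1) and reported with a
#' warning, so a constant sensor never produces NaN downstream.
#'
#' @param values Numeric matrix (observations x variables).
#' @return A list with `values` (the scaled matrix), `center` and `scale`
#'   (per-column parameters).
#' @export
autoscale <- function(values) {
  values <- as.matrix(values)
  if (!length(values)) stop("cannot autoscale an empty table")
  center <- colMeans(values)
  scl <- apply(values, 2L, stats::sd)
  flat <- !is.finite(scl) | scl == 0
  if (any(flat)) {
    warning("zero-variance column(s) carried with scale 1: ",
            paste(colnames(values)[flat], collapse = ", "))
    scl[flat] <- 1
  }
  scaled <- sweep(sweep(values, 2L, center, "-"), 2L, scl, "/")
  list(values = scaled, center = center, scale = scl)
}

apply_scaling <- function(values, center, scale) {
  sweep(sweep(as.matrix(values), 2L, center, "-"), 2L, scale, "/")
}

#' Compute one NIPALS-PLS component
#'
#' Alternates the classic NIPALS steps on centered/scaled blocks: Y-score
#' `u = Y q`, X-weights `w = X'u/||X'u||`, X-scores `t = X w`, Y-loadings
#' `q = Y't/||Y't||`, until `||t - t_old|| < eps`; then X-loadings
#' `p = X't/(t't)` rescaled to unit length (with `t` and `w` multiplied by
#' `||p||`) and the inner coefficient `b = u't/(t't)`. For a single-column Y
#' the Y-loading is identically 1 and no iteration is performed. The initial
#' Y-score is the Y column of largest variance, a deterministic stand-in for
#' an arbitrary start.
#'
#' @param X Numeric matrix (np x nx), preprocessed.
#' @param Y Numeric matrix (np x ny), preprocessed.
#' @param eps Convergence tolerance on the X-score change.
#' @param max_iter Iteration cap; exceeding it is an error reporting the last
#'   score change.
#' @return A list of class `pls_component` with `w`, `t`, `p`, `q`, `u`, `b`
#'   and the iteration count (`0` for univariate Y).
#' @export
nipals_component <- function(X, Y, eps = 1e-8, max_iter = 100000L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  np <- nrow(X)
  if (np < 2L) stop("need at least 2 observations")
  if (nrow(Y) != np) stop("X and Y must have the same number of rows")
  ny <- ncol(Y)
  if (ny == 1L) {
    q <- 1
    u <- Y[, 1L]
    wraw <- crossprod(X, u)
    nw <- sqrt(sum(wraw^2))
    if (nw < .Machine$double.eps) stop("degenerate data: X'u has zero norm")
    w <- wraw / nw
    t <- drop(X %*% w)
    iterations <- 0L
  } else {
    u <- Y[, which.max(apply(Y, 2L, stats::var))]
    t_old <- rep(Inf, np)
    iterations <- 0L
    repeat {
      wraw <- crossprod(X, u)
      nw <- sqrt(sum(wraw^2))
      if (nw < .Machine$double.eps) stop("degenerate data: X'u has zero norm")
      w <- wraw / nw
      t <- drop(X %*% w)
      qraw <- crossprod(Y, t)
      nq <- sqrt(sum(qraw^2))
      if (nq < .Machine$double.eps) stop("degenerate data: Y't has zero norm")
      q <- qraw / nq
      u <- drop(Y %*% q)
      delta <- sqrt(sum((t - t_old)^2))
      iterations <- iterations + 1L
      if (delta < eps) break
      if (iterations >= max_iter) {
        stop(sprintf("NIPALS did not converge in %d iterations (last ||t - t_old|| = %.3g)",
                     max_iter, delta))
      }
      t_old <- t
    }
  }
  tt <- sum(t^2)
  if (tt < .Machine$double.eps) stop("degenerate data: zero-norm score vector")
  p <- drop(crossprod(X, t)) / tt
  pn <- sqrt(sum(p^2))
  p <- p / pn
  t <- t * pn
  w <- drop(w) * pn
  b <- sum(u * t) / sum(t^2)
  structure(
    list(w = w, t = t, p = p, q = drop(q), u = u, b = b,
         iterations = iterations),
    class = "pls_component"
  )
}

#' Fit a NIPALS-PLS regression model
#'
#' Extracts `n_components` latent variables, deflating both blocks after each
#' (`X <- X - t p'`, `Y <- Y - b t q'`), and assembles the regression
#' coefficient matrix `RC` on the preprocessed scale so that
#' `Yhat_scaled = X_scaled RC'` reproduces the NIPALS fitted values exactly
#' (the corrected weights `W (P'W)^{-1}` enter RC; with per-component deflation
#' the uncorrected product Q B W' is only approximate). X is preprocessed per
#' `config$scaling_policy`; Y is centered, never scaled.
#'
#' @param X Numeric matrix with dimnames, observations x predictors.
#' @param Y Numeric matrix with dimnames, observations x responses (a vector
#'   is accepted and treated as one column).
#' @param n_components Number of latent variables; must not exceed the rank of
#'   the preprocessed X.
#' @param config A [plp_config()] supplying `eps_convergence`,
#'   `max_nipals_iter` and `scaling_policy`.
#' @return An object of class `pls_model` with components, `RC`, scaling
#'   parameters and per-component cumulative explained variance of X and Y
#'   (percent, on the preprocessed scale).
#' @export
fit_pls <- function(X, Y, n_components, config = plp_config()) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L, dimnames = list(names(Y), "y"))
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y))) {
    stop("X and Y row labels do not match")
  }
  if (n_components < 1L) stop("n_components must be a positive integer")

  if (config$scaling_policy == "autoscale_X") {
    xs <- autoscale(X)
  } else {
    xs <- list(values = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  }
  y_center <- colMeans(Y)
  Ys <- sweep(Y, 2L, y_center, "-")
  Xw <- xs$values
  Yw <- Ys

  rank_x <- qr(Xw)$rank
  if (n_components > rank_x) {
    stop(sprintf("n_components (%d) exceeds the rank of the preprocessed X (%d)",
                 n_components, rank_x))
  }

  ssx0 <- sum(Xw^2)
  ssy0 <- sum(Yw^2)
  if (ssy0 == 0) stop("Y has no variance")
  comps <- vector("list", n_components)
  cum_var_x <- cum_var_y <- numeric(n_components)
  t0norm <- NA_real_
  k_done <- 0L
  for (k in seq_len(n_components)) {
    comp <- nipals_component(Xw, Yw, eps = config$eps_convergence,
                             max_iter = config$max_nipals_iter)
    tnorm <- sqrt(sum(comp$t^2))
    if (is.na(t0norm)) t0norm <- tnorm
    if (tnorm < 1e-12 * t0norm) break  # rank guard: no structure left
    comps[[k]] <- comp
    Xw <- Xw - tcrossprod(comp$t, comp$p)
    Yw <- Yw - comp$b * tcrossprod(comp$t, comp$q)
    cum_var_x[k] <- 100 * (1 - sum(Xw^2) / ssx0)
    cum_var_y[k] <- 100 * (1 - sum(Yw^2) / ssy0)
    k_done <- k
  }
  if (k_done == 0L) stop("no valid PLS component could be extracted")
  comps <- comps[seq_len(k_done)]
  W <- vapply(comps, `[[`, numeric(ncol(X)), "w")
  P <- vapply(comps, `[[`, numeric(ncol(X)), "p")
  Q <- matrix(vapply(comps, function(c) as.numeric(c$q), numeric(ncol(Y))),
              nrow = ncol(Y))
  bvec <- vapply(comps, `[[`, numeric(1), "b")
  W <- matrix(W, ncol = k_done)
  P <- matrix(P, ncol = k_done)
  # corrected weights: T = X_scaled %*% Wstar, exactly
  Wstar <- W %*% solve(crossprod(P, W))
  RC <- Q %*% diag(bvec, nrow = k_done) %*% t(Wstar)
  dimnames(RC) <- list(colnames(Y), colnames(X))
  structure(
    list(
      components = comps,
      n_components = k_done,
      n_requested = as.integer(n_components),
      RC = RC,
      x_center = xs$center, x_scale = xs$scale,
      y_center = y_center,
      x_names = colnames(X), y_names = colnames(Y),
      cum_var_x_pct = cum_var_x[seq_len(k_done)],
      cum_var_y_pct = cum_var_y[seq_len(k_done)]
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("NIPALS-PLS model: %d latent variable(s), %d predictors, %d response(s)\n",
              x$n_components, length(x$x_center), length(x$y_center)))
  cat(sprintf("  cumulative %%Var X: %s\n",
              paste(sprintf("%.1f", x$cum_var_x_pct), collapse = " ")))
  cat(sprintf("  cumulative %%Var Y: %s\n",
              paste(sprintf("%.1f", x$cum_var_y_pct), collapse = " ")))
  invisible(x)
}

#' Predict responses from a fitted PLS model
#'
#' Applies the training preprocessing to `X_new`, multiplies by the regression
#' coefficients and restores the original response units.
#'
#' @param model A `pls_model` from [fit_pls()].
#' @param X_new Numeric matrix whose columns match the training predictors.
#' @return Matrix of predictions (rows of `X_new` x responses).
#' @export
pls_predict <- function(model, X_new) {
  stopifnot(inherits(model, "pls_model"))
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new)) && !is.null(model$x_names)) {
    missing_cols <- setdiff(model$x_names, colnames(X_new))
    extra <- setdiff(colnames(X_new), model$x_names)
    if (length(missing_cols) || length(extra)) {
      stop("predictor columns do not match training columns; missing: [",
           paste(missing_cols, collapse = ", "), "], extra: [",
           paste(extra, collapse = ", "), "]")
    }
    X_new <- X_new[, model$x_names, drop = FALSE]
  } else if (ncol(X_new) != length(model$x_center)) {
    stop("X_new has ", ncol(X_new), " columns; model expects ",
         length(model$x_center))
  }
  Xs <- apply_scaling(X_new, model$x_center, model$x_scale)
  Yhat <- Xs %*% t(model$RC)
  Yhat <- sweep(Yhat, 2L, model$y_center, "+")
  dimnames(Yhat) <- list(rownames(X_new), model$y_names)
  Yhat
}

#' Percentage of explained variance
#'
#' `100 * (1 - sum((Y - Yhat)^2) / sum(Y^2))`, evaluated on matrices already on
#' the modelling scale (centered response). Can be negative for predictions
#' worse than zero.
#'
#' @param Y Reference matrix.
#' @param Yhat Prediction matrix of the same shape.
#' @return A single percentage.
#' @export
explained_variance_pct <- function(Y, Yhat) {
  Y <- as.matrix(Y)
  Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("Y and Yhat must have the same shape")
  ss <- sum(Y^2)
  if (ss == 0) stop("explained variance undefined: Y is identically zero")
  100 * (1 - sum((Y - Yhat)^2) / ss)
}
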