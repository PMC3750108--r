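#' Project measured fluxes onto one elementary flux mode
#'
#' Fixing the response loadings of a latent variable to a mode `em`, the
#' corresponding score vector — the mode's weighting factor across
#' observations — is the projection `lambda = R em` (with `em` scaled to unit
#' Euclidean norm first under `unit_norm`). When both `R` columns and `em`
#' are named, they are aligned by name and any mismatch is an error.
#'
#' @param R Numeric matrix, observations x measured fluxes.
#' @param em Numeric vector of mode coefficients over the measured fluxes.
#' @param normalization `"unit_norm"` (default) or `"raw"`.
#' @return Numeric vector of weighting factors, one per observation.
#' @export
project_lambda <- function(R, em, normalization = c("unit_norm", "raw")) {
  normalization <- match.arg(normalization)
  R <- as.matrix(R)
  if (!is.null(names(em)) && !is.null(colnames(R))) {
    if (!setequal(names(em), colnames(R))) {
      stop("reaction order mismatch: em names do not match R columns; missing: [",
           paste(setdiff(colnames(R), names(em)), collapse = ", "), "]")
    }
    em <- em[colnames(R)]
  } else if (length(em) != ncol(R)) {
    stop("em has ", length(em), " entries; R has ", ncol(R), " flux columns")
  }
  if (all(em == 0)) stop("em has no nonzero entry over the measured fluxes")
  if (normalization == "unit_norm") em <- em / sqrt(sum(em^2))
  drop(R %*% em)
}

# Fast inner univariate PLS on preprocessed X (centered y handled here).
# Returns fitted values, per-component weights/loadings and the corrected
# regression coefficient vector needed for prediction.
uni_pls <- function(Xs, y, fac) {
  y_center <- mean(y)
  yw <- y - y_center
  Xw <- Xs
  nx <- ncol(Xs)
  W <- P <- matrix(0, nx, fac)
  b <- numeric(fac)
  fitted <- numeric(length(y))
  k_done <- 0L
  t0 <- NA_real_
  for (k in seq_len(fac)) {
    wraw <- crossprod(Xw, yw)
    nw <- sqrt(sum(wraw^2))
    if (nw < 1e-300) break
    w <- wraw / nw
    t <- drop(Xw %*% w)
    tt <- sum(t^2)
    tn <- sqrt(tt)
    if (is.na(t0)) t0 <- tn
    if (tn < 1e-12 * t0 || tt == 0) break
    p <- drop(crossprod(Xw, t)) / tt
    pn <- sqrt(sum(p^2))
    p <- p / pn
    t <- t * pn
    w <- drop(w) * pn
    bk <- sum(yw * t) / sum(t^2)
    Xw <- Xw - tcrossprod(t, p)
    yw <- yw - bk * t
    W[, k] <- w
    P[, k] <- p
    b[k] <- bk
    fitted <- fitted + bk * t
    k_done <- k
  }
  if (k_done == 0L) {
    return(list(yhat = rep(y_center, length(y)), n_lv = 0L,
                Wstar = matrix(0, nx, 0), P = matrix(0, nx, 0),
                b = numeric(0), rc = numeric(nx), y_center = y_center,
                degenerate = TRUE))
  }
  W <- W[, seq_len(k_done), drop = FALSE]
  P <- P[, seq_len(k_done), drop = FALSE]
  b <- b[seq_len(k_done)]
  Wstar <- W %*% solve(crossprod(P, W))
  list(yhat = fitted + y_center, n_lv = k_done, Wstar = Wstar, P = P, b = b,
       rc = drop(Wstar %*% b), y_center = y_center, degenerate = FALSE)
}

#' Score one candidate EFM against the current flux residual
#'
#' Projects the residual onto the mode (`lambda = R em`), fits an inner
#' univariate PLS of the envirome block onto `lambda` with `config$n_inner_latent`
#' latent variables, and evaluates: the squared Pearson correlation between
#' `lambda` and its prediction with its two-sided p-value (t statistic on
#' `n - 2` degrees of freedom), the explained variance of `lambda`, and the
#' explained variance of the residual flux block by the rank-one
#' reconstruction `lambda_hat em'`. A weighting factor with no variance is not
#' an error: the candidate is scored `r2 = 0`, `p = 1` and flagged degenerate.
#'
#' @param X Numeric matrix, preprocessed envirome block (observations x
#'   variables).
#' @param R_residual Numeric matrix, current centered flux residual.
#' @param em Numeric vector over the residual's flux columns, already
#'   normalized per policy.
#' @param config A [plp_config()].
#' @return A list of class `candidate_score` with `lambda`, `lambda_hat`,
#'   `r2`, `p_value`, `var_lambda_pct`, `var_R_pct`, `n_lv`, `degenerate` and
#'   the fitted inner model.
#' @export
evaluate_candidate <- function(X, R_residual, em, config = plp_config()) {
  X <- as.matrix(X)
  R_residual <- as.matrix(R_residual)
  if (length(em) != ncol(R_residual)) {
    stop("em has ", length(em), " entries; R_residual has ", ncol(R_residual),
         " flux columns")
  }
  np <- nrow(X)
  lambda <- drop(R_residual %*% em)
  ss_cur <- sum(R_residual^2)
  em2 <- sum(em^2)
  if (stats::sd(lambda) < 1e-300 || em2 == 0) {
    lh <- rep(mean(lambda), np)
    var_R <- if (ss_cur > 0) {
      100 * (1 - sum((R_residual - tcrossprod(lh, em))^2) / ss_cur)
    } else 0
    return(structure(list(
      lambda = lambda, lambda_hat = lh,
      r2 = 0, p_value = 1, var_lambda_pct = 0, var_R_pct = var_R,
      n_lv = 0L, degenerate = TRUE, inner = NULL
    ), class = "candidate_score"))
  }
  inner <- uni_pls(X, lambda, config$n_inner_latent)
  lh <- inner$yhat
  sdh <- stats::sd(lh)
  if (sdh < 1e-300 || inner$degenerate) {
    r2 <- 0
    p <- 1
  } else {
    r <- stats::cor(lambda, lh)
    r2 <- r * r
    if (r2 >= 1) {
      p <- 0
    } else {
      tstat <- abs(r) * sqrt((np - 2) / (1 - r2))
      p <- 2 * stats::pt(-tstat, df = np - 2)
    }
  }
  lc <- lambda - mean(lambda)
  var_lambda <- 100 * (1 - sum((lambda - lh)^2) / sum(lc^2))
  sse <- ss_cur - 2 * sum(lh * lambda) + sum(lh^2) * em2
  var_R <- 100 * (1 - sse / ss_cur)
  structure(list(
    lambda = lambda, lambda_hat = lh, r2 = r2, p_value = p,
    var_lambda_pct = var_lambda, var_R_pct = var_R,
    n_lv = inner$n_lv, degenerate = FALSE, inner = inner
  ), class = "candidate_score")
}

#' Select the envirome-correlated subset of elementary flux modes
#'
#' The greedy PLP loop. At each iteration every remaining candidate mode is
#' scored with [evaluate_candidate()] against the current flux residual; the
#' one explaining the most residual variance is taken (ties broken by lower
#' mode id) and accepted only if its weighting factor is well predicted from
#' the envirome (`r2 > r2_threshold`, `p < p_threshold`) and it adds at least
#' `min_variance_gain` of the original flux sum of squares. On acceptance the
#' rank-one reconstruction is deflated from the residual and the mode is
#' removed from the candidate list; selection stops when the best candidate
#' fails the gate, or `max_efms` (or the observation count) is reached.
#'
#' The envirome block is preprocessed once per `config$scaling_policy`; the
#' flux block is column-centered. Each inner univariate PLS restarts from the
#' full envirome block unless `config$deflate_x` is set.
#'
#' @param X Numeric matrix with dimnames, observations x envirome variables.
#' @param R Numeric matrix with dimnames, observations x measured fluxes; row
#'   labels must match `X`.
#' @param efms An [efm_set()] whose reactions cover all columns of `R`.
#' @param config A [plp_config()].
#' @return An object of class `plp_model`: the ordered selections with their
#'   diagnostics and inner models, the weighting-factor matrix `Lambda`, the
#'   selected loadings `EM_selected`, the residual flux block, the cumulative
#'   explained-variance trajectory and the configuration snapshot.
#' @export
select_efms <- function(X, R, efms, config = plp_config()) {
  stopifnot(inherits(efms, "efm_set"))
  X <- as.matrix(X)
  R <- as.matrix(R)
  if (nrow(X) != nrow(R)) stop("X and R must have the same number of rows")
  if (!is.null(rownames(X)) && !is.null(rownames(R)) &&
      !identical(rownames(X), rownames(R))) {
    bad <- which(rownames(X) != rownames(R))[1]
    stop("X and R row labels do not match (first mismatch: '",
         rownames(X)[bad], "' vs '", rownames(R)[bad], "')")
  }
  if (ncol(efms$EM) == 0L) stop("empty EFM set")
  if (is.null(colnames(R))) stop("R must have flux column names")
  miss <- setdiff(colnames(R), efms$reaction_ids)
  if (length(miss)) {
    stop("measured flux column(s) absent from the EFM set: ",
         paste(miss, collapse = ", "))
  }
  np <- nrow(X)
  if (np < config$n_inner_latent + 2L) {
    stop("need at least n_inner_latent + 2 observations")
  }

  V <- efms$EM[match(colnames(R), efms$reaction_ids), , drop = FALSE]
  if (config$efm_normalization == "unit_norm") {
    nrm <- sqrt(colSums(V^2))
    nz <- nrm > 0
    V[, nz] <- sweep(V[, nz, drop = FALSE], 2L, nrm[nz], "/")
  }

  if (config$scaling_policy == "autoscale_X") {
    xs <- autoscale(X)
  } else {
    xs <- list(values = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  }
  Xs <- xs$values
  r_center <- colMeans(R)
  Rc <- sweep(R, 2L, r_center, "-")
  ss0 <- sum(Rc^2)
  if (ss0 == 0) stop("R has no variance")

  R_work <- Rc
  X_work <- Xs
  remaining <- seq_len(ncol(V))
  selected <- list()
  cum_var <- numeric(0)
  Lambda <- matrix(0, np, 0)
  stop_reason <- "max_efms reached"
  iteration_log <- list()

  while (length(selected) < min(config$max_efms, np)) {
    if (!length(remaining)) {
      stop_reason <- "candidate list exhausted"
      break
    }
    scores <- lapply(remaining, function(j) {
      evaluate_candidate(X_work, R_work, V[, j], config)
    })
    vars <- vapply(scores, `[[`, numeric(1), "var_R_pct")
    best_var <- max(vars)
    tie <- which(vars >= best_var - 1e-12)
    pick <- tie[which.min(efms$efm_ids[remaining[tie]])]
    kopt <- remaining[pick]
    sc <- scores[[pick]]
    ss_cur <- sum(R_work^2)
    gain_frac <- (sc$var_R_pct / 100) * ss_cur / ss0
    if (sc$degenerate || sc$r2 <= config$r2_threshold ||
        sc$p_value >= config$p_threshold) {
      stop_reason <- sprintf(
        "best candidate (efm %d) failed the correlation gate (r2 = %.3f, p = %.3g)",
        efms$efm_ids[kopt], sc$r2, sc$p_value)
      break
    }
    if (gain_frac < config$min_variance_gain) {
      stop_reason <- sprintf(
        "explained variance no longer increases (gain %.3g of total SS)",
        gain_frac)
      break
    }
    v <- V[, kopt]
    R_work <- R_work - tcrossprod(sc$lambda_hat, v)
    if (config$deflate_x && sc$inner$n_lv > 0L) {
      Tnew <- X_work %*% sc$inner$Wstar
      X_work <- X_work - tcrossprod(Tnew, sc$inner$P)
    }
    cum_var <- c(cum_var, 100 * (1 - sum(R_work^2) / ss0))
    Lambda <- cbind(Lambda, sc$lambda)
    selected[[length(selected) + 1L]] <- list(
      efm_id = efms$efm_ids[kopt],
      inner = sc$inner,
      em = v,
      score = list(
        r2 = sc$r2, p_value = sc$p_value,
        var_lambda_pct = sc$var_lambda_pct, var_R_pct = sc$var_R_pct,
        n_lv = sc$inner$n_lv,
        neg_lambda_frac = mean(sc$lambda < 0)
      ),
      lambda = sc$lambda, lambda_hat = sc$lambda_hat
    )
    remaining <- remaining[-pick]
  }

  if (length(selected)) {
    colnames(Lambda) <- paste0("efm_", vapply(selected, `[[`, integer(1), "efm_id"))
    rownames(Lambda) <- rownames(X)
  }
  EM_selected <- if (length(selected)) {
    do.call(cbind, lapply(selected, `[[`, "em"))
  } else {
    matrix(0, ncol(R), 0)
  }
  rownames(EM_selected) <- colnames(R)

  structure(
    list(
      selected = selected,
      selected_ids = vapply(selected, `[[`, integer(1), "efm_id"),
      Lambda = Lambda,
      EM_selected = EM_selected,
      residual_R = R_work,
      cum_var_R_pct = cum_var,
      stop_reason = stop_reason,
      config = config,
      x_center = xs$center, x_scale = xs$scale,
      r_center = r_center,
      x_names = colnames(X), flux_names = colnames(R),
      n_obs = np
    ),
    class = "plp_model"
  )
}

#' @export
print.plp_model <- function(x, ...) {
  cat(sprintf("PLP model: %d EFM selected from %d observations\n",
              length(x$selected), x$n_obs))
  if (length(x$selected)) {
    print(selection_table(x), row.names = FALSE, digits = 4)
  }
  cat("stopped:", x$stop_reason, "\n")
  invisible(x)
}

#' Predict measured fluxes from a fitted PLP model
#'
#' Composes the rank-one contributions of the selected modes: each inner model
#' predicts the mode's weighting factor from the (training-scaled) envirome,
#' and `Rhat = sum_k lambda_hat_k em_k' + column means`. With no selected mode
#' the prediction is the column-mean baseline.
#'
#' @param model A `plp_model` from [select_efms()].
#' @param X_new Numeric matrix whose columns match the training envirome
#'   variables.
#' @return Matrix of predicted fluxes in original units.
#' @export
plp_predict <- function(model, X_new) {
  stopifnot(inherits(model, "plp_model"))
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new)) && !is.null(model$x_names)) {
    missing_cols <- setdiff(model$x_names, colnames(X_new))
    extra <- setdiff(colnames(X_new), model$x_names)
    if (length(missing_cols) || length(extra)) {
      stop("envirome columns do not match training columns; missing: [",
           paste(missing_cols, collapse = ", "), "], extra: [",
           paste(extra, collapse = ", "), "]")
    }
    X_new <- X_new[, model$x_names, drop = FALSE]
  } else if (ncol(X_new) != length(model$x_center)) {
    stop("X_new has ", ncol(X_new), " columns; model expects ",
         length(model$x_center))
  }
  Xcur <- apply_scaling(X_new, model$x_center, model$x_scale)
  Rhat <- matrix(0, nrow(X_new), length(model$r_center))
  for (sel in model$selected) {
    inner <- sel$inner
    if (inner$n_lv > 0L) {
      Tnew <- Xcur %*% inner$Wstar
      lh <- drop(Tnew %*% inner$b) + inner$y_center
      if (model$config$deflate_x) {
        Xcur <- Xcur - tcrossprod(Tnew, inner$P)
      }
    } else {
      lh <- rep(inner$y_center, nrow(X_new))
    }
    Rhat <- Rhat + tcrossprod(lh, sel$em)
  }
  Rhat <- sweep(Rhat, 2L, model$r_center, "+")
  dimnames(Rhat) <- list(rownames(X_new), model$flux_names)
  Rhat
}
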