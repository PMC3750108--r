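# Deterministic per-run child seed from a master seed: a counter scheme, so
# adding runs never changes earlier runs.
child_seed <- function(master, i) {
  as.integer((as.double(master) %% 1000003 + 1) * 7919 + i * 104729) %% 2147483647L
}

# One half-sized calibration index draw, stratified by experiment when given.
draw_split <- function(np, experiment = NULL) {
  if (is.null(experiment)) {
    sort(sample.int(np, floor(np / 2)))
  } else {
    stopifnot(length(experiment) == np)
    idx <- integer(0)
    carry <- 0
    for (lev in unique(experiment)) {
      members <- which(experiment == lev)
      want <- (length(members) + carry) / 2
      take <- floor(want)
      carry <- (length(members) + carry) - 2 * take
      idx <- c(idx, sample(members, take))
    }
    sort(idx)
  }
}

#' Bootstrap PLP and PLS over random calibration/validation partitions
#'
#' Repeats the whole fit `n_runs` times: each run draws a random half/half
#' split of the observations (stratified by `experiment` when provided, so
#' every bioreactor run contributes to both partitions), fits PLP and a
#' full-component PLS on the calibration half, and evaluates both on the
#' validation half. Everything is recorded per run: the selected mode ids, the
#' inner regression-coefficient vectors, and calibration/validation explained
#' flux variance for both models (computed on the calibration-centered scale,
#' so the two models are compared on identical footing). Fully reproducible
#' from `seed`; run `i` depends only on `(seed, i)`.
#'
#' @param X Envirome matrix (observations x variables, dimnames required).
#' @param R Flux matrix (observations x fluxes, same rows as X).
#' @param efms An [efm_set()] covering `R`'s columns.
#' @param config A [plp_config()].
#' @param n_runs Number of bootstrap repetitions (`z`).
#' @param seed Master seed.
#' @param experiment Optional vector of experiment labels for stratified
#'   splitting.
#' @param pls_components Latent-variable count for the comparison PLS; default
#'   `NULL` uses the full rank of the calibration envirome block.
#' @return An object of class `bootstrap_result` with one record per run.
#' @export
run_bootstrap <- function(X, R, efms, config = plp_config(), n_runs = 200L,
                          seed = 1L, experiment = NULL,
                          pls_components = NULL) {
  X <- as.matrix(X)
  R <- as.matrix(R)
  np <- nrow(X)
  if (np < 2 * (config$n_inner_latent + 2L)) {
    stop("too few observations for half/half partitioning")
  }
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(child_seed(seed, i))
    cal <- draw_split(np, experiment)
    val <- setdiff(seq_len(np), cal)
    Xc <- X[cal, , drop = FALSE]
    Rc <- R[cal, , drop = FALSE]
    Xv <- X[val, , drop = FALSE]
    Rv <- R[val, , drop = FALSE]

    plp <- select_efms(Xc, Rc, efms, config)
    r_center <- plp$r_center
    cal_plp <- utils::tail(c(0, plp$cum_var_R_pct), 1)
    Rv_c <- sweep(Rv, 2L, r_center, "-")
    val_plp <- explained_variance_pct(Rv_c,
                                      sweep(plp_predict(plp, Xv), 2L, r_center, "-"))

    ncomp <- pls_components
    if (is.null(ncomp)) {
      xs <- if (config$scaling_policy == "autoscale_X") autoscale(Xc)$values else Xc
      ncomp <- qr(xs)$rank
    }
    pls <- fit_pls(Xc, Rc, n_components = ncomp, config = config)
    Rc_c <- sweep(Rc, 2L, pls$y_center, "-")
    cal_pls <- explained_variance_pct(
      Rc_c, sweep(pls_predict(pls, Xc), 2L, pls$y_center, "-"))
    Rv_cp <- sweep(Rv, 2L, pls$y_center, "-")
    val_pls <- explained_variance_pct(
      Rv_cp, sweep(pls_predict(pls, Xv), 2L, pls$y_center, "-"))

    coef_list <- lapply(plp$selected, function(sel) sel$inner$rc)
    names(coef_list) <- paste0("efm_", plp$selected_ids)

    runs[[i]] <- list(
      seed = child_seed(seed, i),
      calibration = cal, validation = val,
      selected = plp$selected_ids,
      coefficients = coef_list,
      cal_var_plp = cal_plp, val_var_plp = val_plp,
      cal_var_pls = cal_pls, val_var_pls = val_pls,
      n_pls_components = pls$n_components
    )
  }
  structure(
    list(n_runs = n_runs, master_seed = as.integer(seed), runs = runs,
         x_names = colnames(X), config = config),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  wins <- sum(vapply(x$runs, function(r) r$val_var_plp > r$val_var_pls, logical(1)))
  cat(sprintf("Bootstrap over %d runs (master seed %d)\n", x$n_runs, x$master_seed))
  cat(sprintf("  PLP beat PLS on validation variance in %d/%d runs\n",
              wins, x$n_runs))
  invisible(x)
}

#' EFM selection frequencies across bootstrap runs
#'
#' Frequency is the selection count divided by the total number of runs.
#'
#' @param result A `bootstrap_result`.
#' @param all_efm_ids Optional full id vector; when given, never-selected
#'   modes appear with frequency 0.
#' @return Data frame `(efm_id, count, frequency)` sorted by decreasing
#'   frequency, ties by id.
#' @export
selection_frequency <- function(result, all_efm_ids = NULL) {
  stopifnot(inherits(result, "bootstrap_result"))
  if (!length(result$runs)) stop("empty bootstrap result")
  sel <- unlist(lapply(result$runs, `[[`, "selected"))
  counts <- table(factor(sel, levels = sort(unique(c(sel, all_efm_ids)))))
  df <- data.frame(
    efm_id = as.integer(names(counts)),
    count = as.integer(counts),
    frequency = as.numeric(counts) / result$n_runs
  )
  if (is.null(all_efm_ids)) df <- df[df$count > 0, , drop = FALSE]
  df[order(-df$frequency, df$efm_id), , drop = FALSE]
}

#' Bootstrap mean, spread and intervals of PLP regression coefficients
#'
#' For every mode selected in at least two runs, the per-run inner
#' regression-coefficient vectors are summarised by their mean and standard
#' deviation over the runs where the mode was selected, and an interval
#' `mean +/- sd * t(1 - alpha/2, dof)` is attached. The interval's width is
#' set by the run-to-run standard deviation (not the standard error), so it
#' characterises where a coefficient from a random repartition falls. The
#' degrees of freedom follow `dof_policy`: `"global"` uses
#' `n_runs - n_inner_latent`; `"per_efm"` uses the mode's own selection count
#' minus the latent-variable count.
#'
#' @param result A `bootstrap_result`.
#' @param alpha Significance level (0.05 gives 95% intervals).
#' @param fac Latent-variable count subtracted in the degrees of freedom;
#'   defaults to the configuration's `n_inner_latent`.
#' @param dof_policy `"global"` (default) or `"per_efm"`.
#' @return Data frame `(efm_id, envirome_var, mean, sd, ci_low, ci_high, n_runs_selected)`.
#' @export
coefficient_confidence <- function(result, alpha = 0.05, fac = NULL,
                                   dof_policy = c("global", "per_efm")) {
  stopifnot(inherits(result, "bootstrap_result"))
  dof_policy <- match.arg(dof_policy)
  if (is.null(fac)) fac <- result$config$n_inner_latent
  sel_all <- unlist(lapply(result$runs, `[[`, "selected"))
  ids <- sort(unique(sel_all))
  out <- list()
  for (id in ids) {
    draws <- lapply(result$runs, function(r) r$coefficients[[paste0("efm_", id)]])
    draws <- draws[!vapply(draws, is.null, logical(1))]
    z_id <- length(draws)
    if (z_id < 2L) {
      warning("efm ", id, " selected in fewer than 2 runs; excluded")
      next
    }
    B <- do.call(rbind, draws)
    bbar <- colMeans(B)
    s <- apply(B, 2L, stats::sd)
    dof <- if (dof_policy == "global") result$n_runs - fac else z_id - fac
    if (dof < 1L) dof <- max(1L, z_id - 1L)
    tq <- stats::qt(1 - alpha / 2, df = dof)
    vars <- result$x_names
    if (is.null(vars)) vars <- paste0("x", seq_along(bbar))
    out[[length(out) + 1L]] <- data.frame(
      efm_id = id, envirome_var = vars,
      mean = bbar, sd = s,
      ci_low = bbar - s * tq, ci_high = bbar + s * tq,
      n_runs_selected = z_id,
      row.names = NULL
    )
  }
  if (!length(out)) {
    return(data.frame(efm_id = integer(0), envirome_var = character(0),
                      mean = numeric(0), sd = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      n_runs_selected = integer(0)))
  }
  do.call(rbind, out)
}
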