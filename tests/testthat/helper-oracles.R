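# Exhaustive elementary-mode oracle: solve the nullspace over every support
# subset, keep one-dimensional sign-feasible solutions. Independent of the
# tableau implementation; tractable up to ~8 reactions.
oracle_efm_keys <- function(net, tol = 1e-9) {
  N <- build_internal_stoichiometry(net)
  q <- ncol(N)
  irr <- !net$reversible
  keys <- character(0)
  for (sz in seq_len(q)) {
    for (S in utils::combn(q, sz, simplify = FALSE)) {
      A <- N[, S, drop = FALSE]
      sv <- svd(A, nu = 0, nv = length(S))
      rank <- sum(sv$d > max(dim(A)) * max(sv$d, 1e-12) * .Machine$double.eps * 64)
      if (length(S) - rank != 1) next
      z <- sv$v[, length(S)]
      if (any(abs(z) < tol)) next  # support must be exactly S
      v <- numeric(q)
      v[S] <- z
      feas_pos <- all(v[irr] >= -tol)
      feas_neg <- all(-v[irr] >= -tol)
      if (!feas_pos && !feas_neg) next
      if (!feas_pos) v <- -v
      if (feas_pos && feas_neg) {
        fz <- which(abs(v) > tol)[1]
        if (v[fz] < 0) v <- -v
      }
      v <- v / min(abs(v[abs(v) > tol]))
      v[abs(v) < tol] <- 0
      keys <- c(keys, paste(sprintf("%.6g", v + 0), collapse = ","))
    }
  }
  sort(keys)
}

efm_set_keys <- function(efms) {
  sort(apply(efms$EM, 2L, function(v) {
    v <- v / min(abs(v[v != 0]))
    paste(sprintf("%.6g", v + 0), collapse = ",")
  }))
}

# Standard synthetic benchmark: a 200-mode reduced-form library with the first
# `n_active` supports disjoint, and a dataset generated from them.
make_benchmark <- function(seed, n_obs = 134L, n_efm = 200L, n_active = 3L,
                           noise_sd_R = 0.05) {
  lib <- generate_efm_library(n_efm = n_efm, n_disjoint = n_active, seed = seed)
  ds <- generate_dataset(lib, generator_spec(
    n_obs = n_obs, active_efm_ids = seq_len(n_active),
    noise_sd_R = noise_sd_R, seed = seed
  ))
  list(lib = lib, ds = ds)
}

random_labelled_matrix <- function(n, p, seed, prefix = "v") {
  set.seed(seed)
  matrix(stats::rnorm(n * p), n, p,
         dimnames = list(sprintf("obs_%03d", seq_len(n)),
                         sprintf("%s%02d", prefix, seq_len(p))))
}

# Build a bootstrap result whose coefficient draws come from a known normal
# distribution: the oracle for the interval arithmetic.
fake_bootstrap <- function(draws_by_run, x_names, n_runs = length(draws_by_run),
                           fac = 4L) {
  structure(
    list(
      n_runs = n_runs, master_seed = 0L,
      runs = lapply(draws_by_run, function(d) {
        list(selected = as.integer(sub("efm_", "", names(d))),
             coefficients = d,
             cal_var_plp = NA_real_, val_var_plp = NA_real_,
             cal_var_pls = NA_real_, val_var_pls = NA_real_)
      }),
      x_names = x_names,
      config = plp_config(n_inner_latent = fac)
    ),
    class = "bootstrap_result"
  )
}

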