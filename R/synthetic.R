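#' Generate a small benchmark metabolic network
#'
#' Three templates:
#' \describe{
#'   \item{`chain`}{a linear pathway `A0_ext -> A1 -> ... -> A(k-1) -> Ak_ext`
#'     of `size` irreversible reactions over `size - 1` internal metabolites;
#'     it has exactly one elementary mode.}
#'   \item{`diamond`}{uptake, two parallel internal routes and excretion; it
#'     has exactly two elementary modes, one per route.}
#'   \item{`bhk_like_random`}{a random mammalian-cell-like network: a core of
#'     internal metabolites connected by random mono/bi-molecular conversions,
#'     uptake and excretion exchanges for a subset of them, and a few
#'     reversible steps. Deterministic in `seed`.}
#' }
#'
#' @param template One of `"chain"`, `"diamond"`, `"bhk_like_random"`.
#' @param size Chain length (chain template) or internal metabolite count
#'   (random template).
#' @param n_reactions Reaction count for the random template.
#' @param seed Seed for the random template.
#' @return A [network_model()].
#' @export
generate_toy_network <- function(template = c("chain", "diamond", "bhk_like_random"),
                                 size = 3L, n_reactions = 35L, seed = 1L) {
  template <- match.arg(template)
  if (template == "chain") {
    k <- as.integer(size)
    if (k < 2L) stop("chain needs at least 2 reactions")
    mets_int <- paste0("A", seq_len(k - 1L))
    mets_ext <- c("A0_ext", paste0("A", k, "_ext"))
    rxn <- paste0("r", seq_len(k))
    stoich <- matrix(0, length(mets_int) + 2L, k,
                     dimnames = list(c(mets_int, mets_ext), rxn))
    stoich["A0_ext", "r1"] <- -1
    stoich["A1", "r1"] <- 1
    for (j in seq_len(k - 2L)) {
      stoich[paste0("A", j), paste0("r", j + 1L)] <- -1
      stoich[paste0("A", j + 1L), paste0("r", j + 1L)] <- 1
    }
    stoich[paste0("A", k - 1L), paste0("r", k)] <- -1
    stoich[paste0("A", k, "_ext"), paste0("r", k)] <- 1
    return(network_model(rxn, stoich, rep(FALSE, k), mets_int, mets_ext))
  }
  if (template == "diamond") {
    mets_int <- c("A", "B")
    mets_ext <- c("A_ext", "B_ext")
    rxn <- c("uptake", "route1", "route2", "excrete")
    stoich <- matrix(0, 4, 4, dimnames = list(c(mets_int, mets_ext), rxn))
    stoich["A_ext", "uptake"] <- -1
    stoich["A", "uptake"] <- 1
    stoich["A", "route1"] <- -1
    stoich["B", "route1"] <- 1
    stoich["A", "route2"] <- -1
    stoich["B", "route2"] <- 1
    stoich["B", "excrete"] <- -1
    stoich["B_ext", "excrete"] <- 1
    return(network_model(rxn, stoich, rep(FALSE, 4), mets_int, mets_ext))
  }
  # bhk_like_random
  m <- as.integer(size)
  if (m < 3L) stop("random network needs at least 3 internal metabolites")
  nr <- as.integer(n_reactions)
  set.seed(seed)
  mets_int <- paste0("M", seq_len(m))
  n_exch <- max(2L, round(m * 0.5))
  exch_mets <- sort(sample.int(m, n_exch))
  mets_ext <- paste0("M", exch_mets, "_ext")
  n_int_rxn <- nr - n_exch
  if (n_int_rxn < m - 1L) stop("too few reactions for the requested size")
  rxn <- character(0)
  rows <- c(mets_int, mets_ext)
  stoich <- matrix(0, length(rows), 0, dimnames = list(rows, NULL))
  add_col <- function(stoich, name, entries) {
    col <- numeric(nrow(stoich))
    names(col) <- rownames(stoich)
    for (nm in names(entries)) col[nm] <- col[nm] + entries[[nm]]
    stoich <- cbind(stoich, col)
    colnames(stoich)[ncol(stoich)] <- name
    stoich
  }
  # exchanges: half uptakes, half excretions
  for (i in seq_along(exch_mets)) {
    met <- paste0("M", exch_mets[i])
    ext <- paste0(met, "_ext")
    nm <- paste0("ex", i)
    if (i %% 2L == 1L) {
      stoich <- add_col(stoich, nm, stats::setNames(list(-1, 1), c(ext, met)))
    } else {
      stoich <- add_col(stoich, nm, stats::setNames(list(-1, 1), c(met, ext)))
    }
    rxn <- c(rxn, nm)
  }
  # a connected backbone, then random extra conversions
  for (j in seq_len(n_int_rxn)) {
    nm <- paste0("v", j)
    if (j < m) {
      sub <- paste0("M", j)
      prod <- paste0("M", j + 1L)
      stoich <- add_col(stoich, nm, stats::setNames(list(-1, 1), c(sub, prod)))
    } else {
      pair <- sample.int(m, 2L)
      n_sub <- sample(1:2, 1)
      subs <- paste0("M", pair[1])
      prods <- paste0("M", pair[2])
      entries <- stats::setNames(list(-n_sub, 1), c(subs, prods))
      stoich <- add_col(stoich, nm, entries)
    }
    rxn <- c(rxn, nm)
  }
  reversible <- rep(FALSE, length(rxn))
  n_rev <- max(1L, round(length(rxn) * 0.15))
  reversible[sample(seq_along(rxn), n_rev)] <- TRUE
  # order: reversible block first, matching the file dialect convention
  ord <- order(!reversible)
  network_model(rxn[ord], stoich[, ord, drop = FALSE], reversible[ord],
                mets_int, mets_ext)
}

#' Generate a library of candidate flux modes in reduced (measured-flux) form
#'
#' Emulates a mode table given over the measured exchange fluxes only: each
#' mode consumes a few compounds and produces a few others (sparse signed
#' coefficients). The first `n_disjoint` modes get mutually disjoint supports,
#' mirroring distinct pathways that touch different parts of the exchange
#' fluxome — these are the natural choices for ground-truth active modes. All
#' supports are distinct; deterministic in `seed`.
#'
#' @param n_fluxes Number of measured fluxes (rows).
#' @param n_efm Number of modes (columns).
#' @param support_range Integer range of support sizes.
#' @param n_disjoint How many leading modes must have pairwise disjoint
#'   supports.
#' @param flux_ids Optional row names; default `flux_01 ...`.
#' @param seed Seed.
#' @return An [efm_set()] in reduced form (no network validation).
#' @export
generate_efm_library <- function(n_fluxes = 24L, n_efm = 200L,
                                 support_range = c(3L, 6L), n_disjoint = 3L,
                                 flux_ids = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(flux_ids)) flux_ids <- sprintf("flux_%02d", seq_len(n_fluxes))
  if (n_disjoint * max(support_range) > n_fluxes) {
    stop("cannot fit ", n_disjoint, " disjoint supports into ", n_fluxes, " fluxes")
  }
  EM <- matrix(0, n_fluxes, n_efm)
  seen <- character(0)
  used <- integer(0)
  for (j in seq_len(n_efm)) {
    repeat {
      ss <- sample(support_range[1]:support_range[2], 1L)
      pool <- if (j <= n_disjoint) setdiff(seq_len(n_fluxes), used) else seq_len(n_fluxes)
      if (length(pool) < ss) ss <- length(pool)
      supp <- sort(sample(pool, ss))
      key <- paste(supp, collapse = ",")
      if (!key %in% seen) break
    }
    seen <- c(seen, key)
    if (j <= n_disjoint) used <- c(used, supp)
    coefs <- stats::runif(length(supp), 0.5, 2) *
      sample(c(-1, 1), length(supp), replace = TRUE)
    # every mode consumes something and produces something
    if (all(coefs > 0)) coefs[1] <- -coefs[1]
    if (all(coefs < 0)) coefs[length(coefs)] <- -coefs[length(coefs)]
    EM[supp, j] <- coefs
  }
  rownames(EM) <- flux_ids
  efm_set(EM, reaction_ids = flux_ids, efm_ids = seq_len(n_efm))
}

#' Specification of a synthetic envirome/fluxome dataset
#'
#' Holds the generator parameters. Defaults mirror the scale of a typical
#' mammalian-cell bioreactor campaign: 134 observations from 7 experiments,
#' 26 envirome variables, a handful of active modes, 5% flux noise.
#'
#' @param n_obs Number of observations.
#' @param n_envirome_vars Number of envirome variables.
#' @param active_efm_ids Ids (within the mode library) of the truly active
#'   modes.
#' @param noise_sd_R Flux noise, relative to the global signal RMS.
#' @param noise_sd_X Envirome noise, relative to each variable's signal SD.
#' @param n_experiments Number of experiment blocks (smooth profiles are drawn
#'   per block).
#' @param n_latent Latent trajectory count per experiment driving the envirome.
#' @param lambda_intercept,lambda_slope Location and spread of the linear
#'   predictor entering the softplus that forms the non-negative weighting
#'   factors.
#' @param seed Seed.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_obs = 134L, n_envirome_vars = 26L,
                           active_efm_ids = 1:3, noise_sd_R = 0.05,
                           noise_sd_X = 0.02, n_experiments = 7L,
                           n_latent = 4L, lambda_intercept = 1,
                           lambda_slope = 0.8, seed = 1L) {
  stopifnot(length(active_efm_ids) >= 1L, noise_sd_R >= 0, noise_sd_X >= 0,
            n_obs >= 4L, n_experiments >= 1L)
  structure(
    list(n_obs = as.integer(n_obs),
         n_envirome_vars = as.integer(n_envirome_vars),
         active_efm_ids = as.integer(active_efm_ids),
         noise_sd_R = noise_sd_R, noise_sd_X = noise_sd_X,
         n_experiments = as.integer(n_experiments),
         n_latent = as.integer(n_latent),
         lambda_intercept = lambda_intercept,
         lambda_slope = lambda_slope,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

#' Generate a synthetic envirome/fluxome dataset with known ground truth
#'
#' The generative model is the PLP model read forwards. Each experiment block
#' evolves a few smooth latent trajectories (random low-order Fourier series
#' in batch time); the envirome `X` is a shared linear mixing of those
#' trajectories plus relative Gaussian noise. Each active mode's weighting
#' factor is a softplus-transformed linear function of the standardized
#' envirome, `lambda_i = softplus(a + X_std c_i)` — softplus keeps the
#' weighting factors non-negative, as convex mode weights must be, at the cost
#' of mild nonlinearity. The fluxes are `R = Lambda EM_active' + noise`, with
#' i.i.d. Gaussian noise whose standard
#' deviation is `noise_sd_R` times the global signal RMS, so the unexplained
#' variance share is `noise_sd_R^2 / (1 + noise_sd_R^2)` by construction.
#'
#' @param efms An [efm_set()] supplying the candidate mode library.
#' @param spec A [generator_spec()].
#' @return A list: `X`, `R` (matrices with matching row labels), `truth` (a
#'   list with `Lambda_true`, `active_efm_ids`, `C`, `seed`), and `experiment`
#'   (block labels).
#' @export
generate_dataset <- function(efms, spec = generator_spec()) {
  stopifnot(inherits(efms, "efm_set"), inherits(spec, "generator_spec"))
  if (!all(spec$active_efm_ids %in% efms$efm_ids)) {
    stop("active_efm_ids not all present in the mode library")
  }
  set.seed(spec$seed)
  np <- spec$n_obs
  nx <- spec$n_envirome_vars
  nblk <- spec$n_experiments
  blk_sizes <- diff(round(seq(0, np, length.out = nblk + 1L)))
  experiment <- rep(seq_len(nblk), blk_sizes)

  # smooth latent trajectories per experiment, shared mixing into the envirome
  nlat <- spec$n_latent
  mixing <- matrix(stats::rnorm(nlat * nx), nlat, nx)
  Xsig <- matrix(0, np, nx)
  row0 <- 0L
  for (b in seq_len(nblk)) {
    nb <- blk_sizes[b]
    tt <- seq(0, 1, length.out = nb)
    G <- matrix(0, nb, nlat)
    for (l in seq_len(nlat)) {
      amp <- stats::rnorm(3)
      ph <- stats::runif(3, 0, 2 * pi)
      G[, l] <- amp[1] * sin(pi * tt + ph[1]) +
        amp[2] * sin(2 * pi * tt + ph[2]) +
        amp[3] * tt
    }
    Xsig[row0 + seq_len(nb), ] <- G %*% mixing
    row0 <- row0 + nb
  }
  sdX <- apply(Xsig, 2L, stats::sd)
  sdX[sdX == 0] <- 1
  X <- Xsig + matrix(stats::rnorm(np * nx), np, nx) *
    rep(spec$noise_sd_X * sdX, each = np)
  rownames(X) <- sprintf("obs_%03d", seq_len(np))
  colnames(X) <- sprintf("env_%02d", seq_len(nx))

  # non-negative weighting factors, linear in the standardized envirome
  Xstd <- scale(X)
  n_act <- length(spec$active_efm_ids)
  C <- matrix(stats::rnorm(n_act * nx), n_act, nx)
  C <- C / sqrt(rowSums(C^2)) * spec$lambda_slope
  Z <- Xstd %*% t(C)
  Z <- sweep(Z, 2L, apply(Z, 2L, stats::sd), "/") * spec$lambda_slope
  Lambda <- softplus(spec$lambda_intercept + Z)
  colnames(Lambda) <- paste0("efm_", spec$active_efm_ids)
  rownames(Lambda) <- rownames(X)

  act_idx <- match(spec$active_efm_ids, efms$efm_ids)
  EM_act <- efms$EM[, act_idx, drop = FALSE]
  Rsig <- Lambda %*% t(EM_act)
  rms <- sqrt(mean(Rsig^2))  # global signal RMS: noise is s * rms everywhere,
  if (rms == 0) rms <- 1     # so the unexplained share is s^2 / (1 + s^2)
  R <- Rsig + matrix(stats::rnorm(np * nrow(efms$EM)), np, nrow(efms$EM)) *
    (spec$noise_sd_R * rms)
  rownames(R) <- rownames(X)
  colnames(R) <- efms$reaction_ids

  list(
    X = X, R = R,
    truth = list(Lambda_true = Lambda, active_efm_ids = spec$active_efm_ids,
                 C = C, seed = spec$seed),
    experiment = experiment
  )
}
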