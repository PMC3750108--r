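#' Construct an elementary flux mode set
#'
#' Container for a matrix of flux modes over a fixed reaction order. Columns
#' are modes; rows are reactions. When a network is supplied the set is
#' validated against it: every mode must satisfy the internal steady-state
#' balance, respect irreversibility signs, and no mode's support may properly
#' contain another's. Mode tables in reduced (measured-flux) form carry no
#' network and skip that validation.
#'
#' @param EM Numeric matrix, reactions x modes.
#' @param reaction_ids Character vector naming the rows.
#' @param efm_ids Integer labels for the columns (default `1:nem`).
#' @param reversible_mode Logical per-mode flag: `TRUE` when the mode as a
#'   whole can run in either direction.
#' @param network Optional [network_model()] used to validate the set.
#' @param tol Numeric tolerance for the steady-state check.
#' @return An object of class `efm_set`.
#' @export
efm_set <- function(EM, reaction_ids, efm_ids = seq_len(ncol(EM)),
                    reversible_mode = rep(FALSE, ncol(EM)),
                    network = NULL, tol = 1e-9) {
  EM <- as.matrix(EM)
  if (length(reaction_ids) != nrow(EM)) {
    stop("reaction_ids must name every row of EM")
  }
  if (length(efm_ids) != ncol(EM)) stop("efm_ids must label every column of EM")
  if (anyDuplicated(efm_ids)) stop("duplicate efm_ids")
  if (length(reversible_mode) != ncol(EM)) {
    stop("reversible_mode must flag every column of EM")
  }
  if (!is.null(network)) {
    stopifnot(inherits(network, "network_model"))
    if (!identical(as.character(reaction_ids), network$reaction_ids)) {
      stop("reaction_ids do not match the network's reaction order")
    }
    N <- build_internal_stoichiometry(network)
    resid <- N %*% EM
    if (max(abs(resid)) > tol * max(1, max(abs(EM)))) {
      stop("mode(s) violate the internal steady-state balance")
    }
    irr <- !network$reversible
    if (any(EM[irr, , drop = FALSE] < -tol)) {
      stop("mode(s) carry negative flux through irreversible reaction(s)")
    }
    supp <- EM != 0
    nem <- ncol(EM)
    for (i in seq_len(nem)) {
      for (j in seq_len(nem)) {
        if (i != j && all(supp[supp[, j], i]) && sum(supp[, i]) > sum(supp[, j])) {
          stop(sprintf("support of mode %d properly contains support of mode %d",
                       efm_ids[i], efm_ids[j]))
        }
      }
    }
  }
  structure(
    list(
      efm_ids = as.integer(efm_ids),
      EM = unname(EM),
      reaction_ids = as.character(reaction_ids),
      reversibility_tags = as.logical(reversible_mode)
    ),
    class = "efm_set"
  )
}

#' @export
print.efm_set <- function(x, ...) {
  cat(sprintf("EFM set: %d modes over %d reactions (%d reversible modes)\n",
              ncol(x$EM), nrow(x$EM), sum(x$reversibility_tags)))
  invisible(x)
}

# Smallest integer d <= limit with x*d integral (within tol), via the Stern-
# Brocot / continued-fraction expansion; NA when none exists.
denominator_of <- function(x, limit = 1e6, tol = 1e-9) {
  x <- abs(x)
  frac <- x - floor(x)
  if (frac < tol) return(1)
  # continued fraction convergents of frac
  a <- frac
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- floor(1 / a)
  # iterate convergents of frac = [0; a1, a2, ...]
  num0 <- 0; den0 <- 1; num1 <- 1; den1 <- 0
  val <- frac
  for (it in 1:64) {
    ai <- floor(val)
    num2 <- ai * num1 + num0
    den2 <- ai * den1 + den0
    if (den2 > limit) return(NA_real_)
    if (abs(frac * den2 - round(frac * den2)) < tol * max(1, den2)) {
      return(den2)
    }
    rem <- val - ai
    if (rem < 1e-15) return(NA_real_)
    val <- 1 / rem
    num0 <- num1; den0 <- den1; num1 <- num2; den1 <- den2
  }
  NA_real_
}

gcd2 <- function(a, b) {
  while (b != 0) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  a
}

# Reduce an integer-valued numeric vector by the gcd of its nonzero entries.
gcd_reduce <- function(v) {
  v[v == 0] <- 0  # normalize negative zeros so row keys compare equal
  nz <- abs(v[v != 0])
  if (!length(nz)) return(v)
  g <- nz[1]
  for (x in nz[-1]) {
    g <- gcd2(g, x)
    if (g == 1) break
  }
  v / g
}

# Scale every column of N to integer entries (exact rational arithmetic needs
# an integer tableau). Errors when a coefficient has no small denominator.
integerize_columns <- function(N, limit = 1e6) {
  for (j in seq_len(ncol(N))) {
    col <- N[, j]
    dens <- vapply(col[col != 0], denominator_of, numeric(1), limit = limit)
    if (anyNA(dens)) {
      stop("stoichiometric coefficient in reaction column ", j,
           " is not a small rational; exact enumeration needs rational inputs")
    }
    d <- 1
    for (x in dens) d <- d / gcd2(d, x) * x
    col <- round(col * d)
    N[, j] <- gcd_reduce(col)
  }
  N
}

#' Enumerate the elementary flux modes of a small network
#'
#' Computes the support-minimal generating vectors of the steady-state flux
#' cone `{r : N r = 0, r_irrev >= 0}` by the classical tableau (double
#' description) algorithm with support-minimality tests, in exact integer
#' arithmetic. Each reversible reaction is split into a forward and a backward
#' irreversible column — in the all-irreversible tableau the support of a
#' combined row is exactly the union of its parents' supports, which makes the
#' classical adjacency pre-test sound — and the modes are mapped back
#' afterwards: the two-cycle artifacts are removed and a fully reversible mode
#' (both orientations feasible) is reported once, canonically oriented with
#' its first nonzero coefficient positive. Output modes are scaled so the
#' smallest nonzero absolute coefficient is 1 and columns are sorted
#' lexicographically by support and then by coefficients, making mode ids
#' stable across runs.
#'
#' Intended for small networks (tens of reactions, up to roughly 1e4 modes);
#' exceeding `max_modes` intermediate rows raises a resource error rather than
#' silently truncating.
#'
#' @param network A validated [network_model()].
#' @param max_modes Cap on tableau rows at any step.
#' @return An `efm_set` over the network's reactions.
#' @export
enumerate_efms <- function(network, max_modes = 100000L) {
  stopifnot(inherits(network, "network_model"))
  N <- build_internal_stoichiometry(network)
  N <- integerize_columns(N)
  q <- ncol(N)
  m <- nrow(N)
  rev <- network$reversible
  # split reversible reactions: columns 1..q run forward, appended columns run
  # the reversible reactions backward
  Nx <- cbind(N, -N[, rev, drop = FALSE])
  qx <- ncol(Nx)
  orig_of <- c(seq_len(q), which(rev))
  direction <- c(rep(1, q), rep(-1, sum(rev)))
  # tableau rows: [reaction part | internal metabolite part]; the metabolite
  # part of a row is always Nx %*% (reaction part)
  Tm <- cbind(diag(qx), t(Nx))
  big <- 2^49

  for (jm in seq_len(m)) {
    col <- qx + jm
    a <- Tm[, col]
    zero_rows <- which(a == 0)
    nz <- which(a != 0)
    if (!length(nz)) {
      next
    }
    pos <- nz[a[nz] > 0]
    neg <- nz[a[nz] < 0]
    new_rows <- list()
    supp <- Tm[, seq_len(qx), drop = FALSE] != 0
    for (i in pos) {
      for (k in neg) {
        # adjacency pre-test: the combination is non-elementary when another
        # current row's reaction support fits inside the parents' union
        u <- supp[i, ] | supp[k, ]
        cnt <- supp %*% as.numeric(!u)
        inside <- which(cnt == 0)
        if (length(setdiff(inside, c(i, k)))) next
        v <- (-a[k]) * Tm[i, ] + a[i] * Tm[k, ]
        if (max(abs(v)) >= big) {
          stop("integer overflow in tableau; network too ill-conditioned")
        }
        new_rows[[length(new_rows) + 1L]] <- gcd_reduce(v)
      }
    }
    Tm <- rbind(Tm[zero_rows, , drop = FALSE],
                do.call(rbind, c(list(NULL), new_rows)))
    if (nrow(Tm) == 0L) break
    # deduplicate: gcd-reduced nonnegative integer rows proportional to each
    # other are identical
    keys <- apply(Tm[, seq_len(qx), drop = FALSE], 1L, paste, collapse = ",")
    Tm <- Tm[!duplicated(keys), , drop = FALSE]
    if (nrow(Tm) > max_modes) {
      stop("enumeration exceeded the cap of ", max_modes,
           " intermediate modes; raise max_modes or reduce the network")
    }
  }

  if (nrow(Tm) == 0L) {
    return(efm_set(matrix(0, q, 0), network$reaction_ids, integer(0),
                   logical(0), network = NULL))
  }
  Ex <- Tm[, seq_len(qx), drop = FALSE]
  # drop rows running any reversible reaction in both directions at once (the
  # two-cycle artifacts of the split and anything containing them)
  uses_both <- apply(Ex, 1L, function(e) {
    both <- tapply(e != 0, orig_of, sum)
    any(both > 1)
  })
  Ex <- Ex[!uses_both, , drop = FALSE]
  if (nrow(Ex) == 0L) {
    return(efm_set(matrix(0, q, 0), network$reaction_ids, integer(0),
                   logical(0), network = NULL))
  }
  # map back to net fluxes over the original reactions
  EM <- matrix(0, q, nrow(Ex))
  for (cidx in seq_len(qx)) {
    EM[orig_of[cidx], ] <- EM[orig_of[cidx], ] + direction[cidx] * Ex[, cidx]
  }
  # a mode whose support lies entirely on reversible reactions is reversible
  # as a whole and was found in both orientations: orient and deduplicate
  revclass <- apply(EM != 0, 2L, function(s) all(rev[s]))
  for (j in which(revclass)) {
    v <- EM[, j]
    if (v[which(v != 0)[1]] < 0) EM[, j] <- -v
  }
  EM[EM == 0] <- 0
  keys <- apply(EM, 2L, paste, collapse = ",")
  dup <- duplicated(keys)
  EM <- EM[, !dup, drop = FALSE]
  revclass <- revclass[!dup]

  # final exact elementarity filter: a mode is elementary iff the nullspace of
  # the internal stoichiometry restricted to its support is one-dimensional
  keep <- vapply(seq_len(ncol(EM)), function(j) {
    S <- which(EM[, j] != 0)
    length(S) - qr(N[, S, drop = FALSE])$rank == 1L
  }, logical(1))
  EM <- EM[, keep, drop = FALSE]
  revclass <- revclass[keep]

  # canonical scaling: smallest nonzero |coefficient| is 1
  for (j in seq_len(ncol(EM))) {
    v <- EM[, j]
    EM[, j] <- v / min(abs(v[v != 0]))
  }
  EM[EM == 0] <- 0
  # canonical order: lexicographic by support pattern, then by coefficients
  supp_key <- apply(EM != 0, 2L, function(s) paste(as.integer(s), collapse = ""))
  coef_key <- apply(EM, 2L, function(v) paste(sprintf("%.12g", v), collapse = ","))
  ord <- order(supp_key, coef_key, method = "radix")
  EM <- EM[, ord, drop = FALSE]
  revclass <- revclass[ord]

  efm_set(EM, network$reaction_ids, seq_len(ncol(EM)), revclass,
          network = network)
}

# Orthonormal basis of the nullspace of A (columns), via SVD.
nullspace_basis <- function(A, tol = NULL) {
  if (ncol(A) == 0L) return(matrix(0, 0, 0))
  if (nrow(A) == 0L) return(diag(ncol(A)))
  sv <- svd(A, nu = 0, nv = ncol(A))
  if (is.null(tol)) tol <- max(dim(A)) * max(sv$d, 0) * .Machine$double.eps * 64
  rank <- sum(sv$d > tol)
  if (rank == ncol(A)) return(matrix(0, ncol(A), 0))
  sv$v[, (rank + 1L):ncol(A), drop = FALSE]
}

#' Test whether a steady-state flux vector is elementary
#'
#' A flux vector is elementary when no other sign-feasible steady-state vector
#' has support strictly contained in its support; equivalently, when the
#' nullspace of the internal stoichiometry restricted to the vector's support
#' is one-dimensional. When the vector is decomposable, a certificate — a
#' sign-feasible steady-state vector with strictly smaller support — is
#' returned.
#'
#' @param candidate Numeric flux vector over the network's reactions.
#' @param network A [network_model()].
#' @param tol Numeric tolerance for steady-state and sign checks.
#' @return A list with elements `elementary` (logical) and `certificate`
#'   (a flux vector, or `NULL` when elementary).
#' @export
is_elementary <- function(candidate, network, tol = 1e-8) {
  stopifnot(inherits(network, "network_model"))
  N <- build_internal_stoichiometry(network)
  q <- ncol(N)
  if (length(candidate) != q) {
    stop("candidate must have one flux per reaction (", q, ")")
  }
  scale <- max(abs(candidate))
  if (scale == 0) stop("candidate is the zero vector")
  if (max(abs(N %*% candidate)) > tol * max(1, scale)) {
    stop("candidate violates the steady-state balance")
  }
  irr <- !network$reversible
  if (any(candidate[irr] < -tol * max(1, scale))) {
    stop("candidate carries negative flux through an irreversible reaction")
  }
  S <- which(abs(candidate) > tol * scale)
  A <- N[, S, drop = FALSE]
  Z <- nullspace_basis(A)
  if (ncol(Z) <= 1L) {
    return(list(elementary = TRUE, certificate = NULL))
  }
  # decomposable: cancel one support component while staying sign-feasible
  vS <- candidate[S]
  for (jz in seq_len(ncol(Z))) {
    z <- Z[, jz]
    z <- z - sum(z * vS) / sum(vS * vS) * vS  # not parallel to the candidate
    if (max(abs(z)) < tol) next
    thetas <- vS[z != 0] / z[z != 0]
    for (th in unique(thetas)) {
      w <- vS - th * z
      w[abs(w) < tol * max(abs(w), scale)] <- 0
      if (all(w == 0) || sum(w != 0) >= length(S)) next
      for (orient in c(1, -1)) {
        full <- numeric(q)
        full[S] <- orient * w
        if (all(full[irr] >= -tol * max(abs(full)))) {
          return(list(elementary = FALSE, certificate = full))
        }
      }
    }
  }
  # nullspace dimension > 1 guarantees decomposability; reaching this point
  # means the numerical search failed
  stop("candidate is decomposable but no certificate was found numerically")
}
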