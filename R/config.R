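#' Run configuration for PLP and PLS fits
#'
#' Bundles every tunable parameter of the pipeline. Defaults follow standard
#' practice for envirome-scale data: four inner latent variables, an r-squared
#' acceptance threshold of 0.75 with a 5% correlation-test significance level,
#' and a NIPALS convergence tolerance of 1e-8.
#'
#' @param n_inner_latent Number of latent variables (`Fac`) of each inner
#'   univariate PLS model, and the default component count for plain PLS.
#' @param r2_threshold Minimum squared Pearson correlation between an EFM
#'   weighting factor and its envirome prediction for the EFM to be accepted.
#'   In (0, 1].
#' @param p_threshold Maximum two-sided p-value of that correlation. In (0, 1).
#' @param max_efms Hard cap on the number of EFM a PLP fit may select.
#' @param eps_convergence NIPALS convergence tolerance on `||t - t_old||`.
#' @param max_nipals_iter Iteration cap for one NIPALS component;
#'   non-convergence is an error.
#' @param min_variance_gain Minimum gain in explained flux variance (fraction
#'   of the original sum of squares) an accepted EFM must deliver;
#'   operationalizes "the explained variance does not increase any further".
#' @param seed Integer seed recorded with the configuration.
#' @param scaling_policy `"autoscale_X"` (center X columns and scale them to
#'   unit variance; the default) or `"raw"` (no X preprocessing). The response
#'   block is always centered, never scaled.
#' @param efm_normalization `"unit_norm"` (candidate EFM scaled to unit
#'   Euclidean norm over the measured fluxes before projection, so explained
#'   variance comparisons are invariant to the arbitrary scaling of modes) or
#'   `"raw"`.
#' @param deflate_x If `TRUE`, the envirome block is deflated by each accepted
#'   inner model's X-decomposition before scoring further EFM. Default `FALSE`:
#'   every inner univariate PLS restarts from the full envirome block.
#'
#' @return An object of class `plp_config` (a validated list).
#' @export
#' @examples
#' cfg <- plp_config(n_inner_latent = 4)
#' cfg$r2_threshold
plp_config <- function(n_inner_latent = 4L,
                       r2_threshold = 0.75,
                       p_threshold = 0.05,
                       max_efms = 100L,
                       eps_convergence = 1e-8,
                       max_nipals_iter = 100000L,
                       min_variance_gain = 1e-6,
                       seed = 1L,
                       scaling_policy = c("autoscale_X", "raw"),
                       efm_normalization = c("unit_norm", "raw"),
                       deflate_x = FALSE) {
  scaling_policy <- match.arg(scaling_policy)
  efm_normalization <- match.arg(efm_normalization)
  stopifnot(
    is.numeric(n_inner_latent), length(n_inner_latent) == 1L, n_inner_latent >= 1,
    n_inner_latent == as.integer(n_inner_latent),
    is.numeric(r2_threshold), length(r2_threshold) == 1L,
    r2_threshold > 0, r2_threshold <= 1,
    is.numeric(p_threshold), length(p_threshold) == 1L,
    p_threshold > 0, p_threshold < 1,
    is.numeric(max_efms), length(max_efms) == 1L, max_efms >= 1,
    is.numeric(eps_convergence), eps_convergence > 0,
    is.numeric(max_nipals_iter), max_nipals_iter >= 1,
    is.numeric(min_variance_gain), min_variance_gain >= 0,
    is.numeric(seed), length(seed) == 1L,
    is.logical(deflate_x), length(deflate_x) == 1L
  )
  structure(
    list(
      n_inner_latent = as.integer(n_inner_latent),
      r2_threshold = r2_threshold,
      p_threshold = p_threshold,
      max_efms = as.integer(max_efms),
      eps_convergence = eps_convergence,
      max_nipals_iter = as.integer(max_nipals_iter),
      min_variance_gain = min_variance_gain,
      seed = as.integer(seed),
      scaling_policy = scaling_policy,
      efm_normalization = efm_normalization,
      deflate_x = deflate_x
    ),
    class = "plp_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [plp_config()]; absent keys take the defaults.
#' Unknown keys are an error so that typos never silently revert a parameter.
#'
#' @param path Path to a YAML file.
#' @return A `plp_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(plp_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(plp_config, raw)
}

#' @export
print.plp_config <- function(x, ...) {
  cat("PLP run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
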