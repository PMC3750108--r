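test_that("bootstrap runs are a pure function of data and seed", {
  bm <- make_benchmark(seed = 60, n_obs = 60, n_efm = 40)
  cfg <- plp_config()
  a <- run_bootstrap(bm$ds$X, bm$ds$R, bm$lib, cfg, n_runs = 2, seed = 7,
                     experiment = bm$ds$experiment)
  b <- run_bootstrap(bm$ds$X, bm$ds$R, bm$lib, cfg, n_runs = 2, seed = 7,
                     experiment = bm$ds$experiment)
  expect_identical(a, b)
  c <- run_bootstrap(bm$ds$X, bm$ds$R, bm$lib, cfg, n_runs = 2, seed = 8,
                     experiment = bm$ds$experiment)
  expect_false(identical(a$runs[[1]]$calibration, c$runs[[1]]$calibration))
  # counter-based child seeds: extending the run count preserves early runs
  d <- run_bootstrap(bm$ds$X, bm$ds$R, bm$lib, cfg, n_runs = 3, seed = 7,
                     experiment = bm$ds$experiment)
  expect_identical(d$runs[1:2], a$runs)
})

test_that("partitions are disjoint, exhaustive and balanced within experiments", {
  bm <- make_benchmark(seed = 61, n_obs = 70, n_efm = 40)
  res <- run_bootstrap(bm$ds$X, bm$ds$R, bm$lib, plp_config(), n_runs = 3,
                       seed = 2, experiment = bm$ds$experiment)
  np <- nrow(bm$ds$X)
  for (r in res$runs) {
    expect_length(intersect(r$calibration, r$validation), 0L)
    expect_setequal(c(r$calibration, r$validation), seq_len(np))
    expect_lte(abs(length(r$calibration) - length(r$validation)), 1L)
    # stratification: each experiment is split near-evenly
    for (b in unique(bm$ds$experiment)) {
      members <- which(bm$ds$experiment == b)
      expect_lte(abs(sum(members %in% r$calibration) -
                       sum(members %in% r$validation)), 1L)
    }
  }
})

test_that("strongly active modes are selected in nearly every run", {
  bm <- make_benchmark(seed = 62)
  res <- run_bootstrap(bm$ds$X, bm$ds$R, bm$lib, plp_config(), n_runs = 10,
                       seed = 3, experiment = bm$ds$experiment)
  freq <- selection_frequency(res)
  top <- freq$frequency[match(1:3, freq$efm_id)]
  expect_true(all(!is.na(top)))
  expect_gte(sum(top >= 0.9), 3L)
})

test_that("selection frequencies equal an independent tally", {
  bm <- make_benchmark(seed = 63, n_obs = 60, n_efm = 40)
  res <- run_bootstrap(bm$ds$X, bm$ds$R, bm$lib, plp_config(), n_runs = 5,
                       seed = 4, experiment = bm$ds$experiment)
  freq <- selection_frequency(res)
  tally <- table(unlist(lapply(res$runs, `[[`, "selected")))
  for (i in seq_len(nrow(freq))) {
    expect_equal(freq$count[i], unname(tally[as.character(freq$efm_id[i])]))
  }
  expect_true(all(freq$frequency >= 0 & freq$frequency <= 1))
  expect_true(!is.unsorted(rev(freq$frequency)))
  # --all style output reports zero-frequency modes
  freq_all <- selection_frequency(res, all_efm_ids = bm$lib$efm_ids)
  expect_equal(nrow(freq_all), length(bm$lib$efm_ids))
  expect_true(any(freq_all$frequency == 0))
})

test_that("identical coefficient draws collapse the interval to a point", {
  d <- stats::setNames(rep(list(list(efm_1 = c(a = 1, b = -2))), 5), NULL)
  res <- fake_bootstrap(d, x_names = c("a", "b"), fac = 2L)
  ci <- coefficient_confidence(res, fac = 2L)
  expect_equal(ci$sd, c(0, 0))
  expect_equal(ci$ci_low, ci$mean)
  expect_equal(ci$ci_high, ci$mean)
})

test_that("intervals from known normal draws match the closed form", {
  set.seed(64)
  z <- 200L
  fac <- 4L
  mu <- 2
  sigma <- 1
  draws <- lapply(seq_len(z), function(i) {
    list(efm_1 = c(v1 = rnorm(1, mu, sigma)))
  })
  res <- fake_bootstrap(draws, x_names = "v1", fac = fac)
  ci <- coefficient_confidence(res, alpha = 0.05, fac = fac)
  expect_equal(ci$mean, mu, tolerance = 0.2 * sigma / sqrt(z) * 5)
  half <- (ci$ci_high - ci$ci_low) / 2
  expect_equal(half, ci$sd * stats::qt(0.975, z - fac), tolerance = 1e-12)
  expect_equal(half, sigma * stats::qt(0.975, z - fac), tolerance = 0.15)
  # stricter alpha widens the interval
  ci01 <- coefficient_confidence(res, alpha = 0.01, fac = fac)
  expect_gt(ci01$ci_high - ci01$ci_low, ci$ci_high - ci$ci_low)
  # per-mode degrees of freedom are exposed
  ci_pe <- coefficient_confidence(res, alpha = 0.05, fac = fac,
                                  dof_policy = "per_efm")
  expect_equal((ci_pe$ci_high - ci_pe$ci_low) / 2,
               ci_pe$sd * stats::qt(0.975, z - fac), tolerance = 1e-12)
})

test_that("modes selected in fewer than two runs are excluded with a warning", {
  draws <- list(
    list(efm_1 = c(v1 = 1), efm_9 = c(v1 = 5)),
    list(efm_1 = c(v1 = 2))
  )
  res <- fake_bootstrap(draws, x_names = "v1", fac = 1L)
  expect_warning(ci <- coefficient_confidence(res, fac = 1L), "fewer than 2")
  expect_equal(unique(ci$efm_id), 1L)
})

test_that("intervals cover replicate coefficient draws at the nominal rate", {
  # the interval uses the run-to-run SD, so its calibration target is a fresh
  # draw from the same resampling distribution
  set.seed(65)
  z <- 200L
  fac <- 4L
  n_coef <- 400L
  vars <- sprintf("v%03d", seq_len(n_coef))
  mus <- stats::setNames(rnorm(n_coef, 0, 3), vars)
  draws <- lapply(seq_len(z), function(i) {
    list(efm_1 = mus + rnorm(n_coef))
  })
  res <- fake_bootstrap(draws, x_names = vars, fac = fac)
  ci <- coefficient_confidence(res, alpha = 0.05, fac = fac)
  fresh <- mus + rnorm(n_coef)
  covered <- fresh >= ci$ci_low & fresh <= ci$ci_high
  expect_gt(mean(covered), 0.95 - 3 * sqrt(0.05 * 0.95 / n_coef))
  # and the true means themselves are essentially always inside: the interval
  # is a spread statement, not a standard error of the mean
  expect_gt(mean(mus >= ci$ci_low & mus <= ci$ci_high), 0.99)
})
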