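# Fits in this file run at deliberately small sizes and reduced MCMC
# settings; they probe direction and consistency, not published-scale
# precision.

perfect_clips <- function(n_rec = 10, n_win = 10, seed = 2) {
  set.seed(seed)
  rows <- list()
  for (k in seq_len(n_rec)) {
    v <- matrix(rpois(n_win * 4, c(2, 1, 2, 1)), n_win, 4, byrow = TRUE)
    rows[[k]] <- tibble::tibble(
      recording_id = sprintf("r%02d", k), clip_id = sprintf("r%02d_c", k),
      window_index = seq_len(n_win) - 1L,
      v_CHI = v[, 1], v_OCH = v[, 2], v_FEM = v[, 3], v_MAL = v[, 4],
      n_CHI = v[, 1], n_OCH = v[, 2], n_FEM = v[, 3], n_MAL = v[, 4]
    )
  }
  dplyr::bind_rows(rows)
}

test_that("a perfect classifier yields a near-identity confusion posterior", {
  clips <- perfect_clips()
  fit <- suppressWarnings(fit_confusion(clips,
    mcmc = mcmc_config(chains = 2, warmup = 300, iter = 300, seed = 4)))
  sp <- speaker_classes()
  for (i in sp) for (j in sp) {
    m <- mean(posterior_draws(fit, sprintf("mu[%s,%s]", i, j)))
    if (i == j) expect_gt(m, 0.75) else expect_lt(m, 0.15)
  }
})

test_that("with no calibration clips the confusion posterior reproduces its prior", {
  empty <- perfect_clips()[0, ]
  fit <- suppressWarnings(fit_confusion(empty,
    mcmc = mcmc_config(chains = 2, warmup = 500, iter = 600, seed = 5)))
  mu_draws <- posterior_draws(fit, "mu[CHI,FEM]")
  expect_lt(abs(median(mu_draws) - log(2)), 0.25)       # Exponential(1)
  expect_lt(abs(mean(mu_draws) - 1), 0.3)
  al_draws <- posterior_draws(fit, "alpha[OCH,MAL]")
  expect_true(all(al_draws >= 1))
  expect_gt(median(al_draws), 1.25)                     # Pareto(1, 1.5)
  expect_lt(median(al_draws), 2.2)
  tau_draws <- posterior_draws(fit, "tau")
  expect_lt(abs(median(tau_draws) - qnorm(0.75)), 0.25) # half-normal(1)
})

test_that("fewer than two informative recordings is an error", {
  clips <- perfect_clips(n_rec = 1)
  expect_error(fit_confusion(clips), "at least 2 recordings")
})

test_that("confusion fits are exactly reproducible under a fixed seed", {
  clips <- perfect_clips(n_rec = 4, n_win = 5)
  cfg <- mcmc_config(chains = 1, warmup = 100, iter = 100, seed = 11)
  f1 <- suppressWarnings(fit_confusion(clips, mcmc = cfg))
  f2 <- suppressWarnings(fit_confusion(clips, mcmc = cfg))
  expect_identical(f1$draws, f2$draws)
})

test_that("doubling the calibration data tightens the confusion posterior", {
  prof <- confusion_profile(mu = diag(4) * 0.7 + 0.05,
                            alpha = matrix(6, 4, 4), tau = 0.8)
  small <- make_calibration_clips(fixture_spec(
    calib_recordings = 4, windows_per_recording = 10, profile = prof,
    window_rates = c(CHI = 2, OCH = 1, FEM = 2, MAL = 1), seed = 21))
  large <- make_calibration_clips(fixture_spec(
    calib_recordings = 8, windows_per_recording = 20, profile = prof,
    window_rates = c(CHI = 2, OCH = 1, FEM = 2, MAL = 1), seed = 21))
  cfg <- mcmc_config(chains = 2, warmup = 250, iter = 250, seed = 6)
  f_small <- suppressWarnings(fit_confusion(small, mcmc = cfg))
  f_large <- suppressWarnings(fit_confusion(large, mcmc = cfg))
  sd_small <- sd(posterior_draws(f_small, "mu[FEM,FEM]"))
  sd_large <- sd(posterior_draws(f_large, "mu[FEM,FEM]"))
  expect_lt(sd_large, sd_small)
})

test_that("joint and naive fits agree in the error-free limit and share one interface", {
  par <- behavior_params()
  truth <- simulate_true_counts(par, 16, 2, seed = 31)
  set.seed(32)
  meas <- apply_classifier(truth, identity_profile(tau = 800))
  clips <- make_calibration_clips(fixture_spec(
    calib_recordings = 4, windows_per_recording = 8,
    profile = identity_profile(tau = 800), seed = 33))
  dataset <- list(recordings = meas, clips = clips)
  cfg <- mcmc_config(chains = 2, warmup = 350, iter = 350, seed = 7)
  nf <- suppressWarnings(naive_fit(dataset, mcmc = cfg))
  jf <- suppressWarnings(fit_joint(dataset, mcmc = cfg, store_v = FALSE))
  for (p in c("beta_sib_adu", "beta_sib_och", "alpha_dev")) {
    dn <- posterior_draws(nf, p)
    dj <- posterior_draws(jf, p)
    pooled <- sqrt(sd(dn)^2 + sd(dj)^2)
    expect_lt(abs(mean(dn) - mean(dj)), 3 * pooled)
  }
})

test_that("incomplete recording metadata is rejected with the offending ids", {
  par <- behavior_params()
  recs <- simulate_true_counts(par, 4, 1, seed = 41)
  recs$age_months[2] <- NA
  expect_error(fit_joint(list(recordings = recs, clips = NULL)),
               recs$recording_id[2])
  recs2 <- simulate_true_counts(par, 4, 1, seed = 41)
  recs2$n_siblings <- NULL
  expect_error(naive_fit(list(recordings = recs2)), "n_siblings")
})

test_that("coverage_calibration returns full-range coverage at level 1", {
  cov <- suppressWarnings(coverage_calibration(
    n_sims = 2, n_children = 5, recordings_per_child = 1,
    calib_recordings = 4, windows_per_recording = 8,
    levels = c(0.5, 1.0),
    mcmc = mcmc_config(chains = 1, warmup = 150, iter = 150), seed = 3))
  expect_equal(nrow(cov), 2L)
  expect_equal(cov$coverage[cov$level == 1], 1)
  expect_true(all(cov$coverage >= 0 & cov$coverage <= 1))
})
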