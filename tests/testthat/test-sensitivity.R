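test_that("an error-free classifier leaves the female-proportion pipeline unbiased", {
  res <- female_proportion_experiment(identity_profile(), n_samples = 300, seed = 2)
  expect_equal(nrow(res), 300L)
  expect_lt(mean(abs(res$theta_meas - res$theta_hat)), 0.01)
})

test_that("FEM-to-CHI leakage manufactures a spurious child-input association under the null", {
  sp <- speaker_classes()
  mu <- diag(4) * 0.7
  mu[3, 1] <- 0.5    # FEM detections leak into CHI
  # high shapes: rates nearly constant across units, so the shared-source
  # covariance is not diluted by rate variability
  leaky <- confusion_profile(mu, matrix(200, 4, 4), tau = 1)
  gen <- function(theta) {
    # theta = 0: truly independent counts across speakers
    n <- 150
    tibble::tibble(CHI = rpois(n, 40), OCH = rpois(n, 10),
                   FEM = rpois(n, 60), MAL = rpois(n, 15))
  }
  cfg <- sensitivity_config(theta_spec = 0, n_replicates = 30, generator = gen,
                            profile = leaky, pipeline = "chi_fem_correlation",
                            seed = 4)
  res <- run_sensitivity(cfg)
  expect_gt(mean(res$theta_meas), 0.1)
  expect_true(all(res$theta_hat == 0))
})

test_that("sensitivity runs are bit-identical under a fixed seed", {
  p <- bundled_profile("precision_biased")
  a <- female_proportion_experiment(p, n_samples = 50, seed = 9)
  b <- female_proportion_experiment(p, n_samples = 50, seed = 9)
  expect_identical(a$theta_meas, b$theta_meas)
})

test_that("unknown pipelines are rejected by name", {
  expect_error(sensitivity_config(0, 5, function(t) NULL,
                                  bundled_profile("recall_biased"),
                                  "no_such_pipeline"),
               "unknown pipeline")
})

test_that("the Monte-Carlo p-value follows the add-one convention", {
  expect_equal(null_test(10, 1:9), 1 / 10)      # above all N = 9 replicates
  expect_equal(null_test(0, 1:9), 1)            # below all replicates
  expect_equal(null_test(5, c(1, 7, 9)), 3 / 4) # ties and order
  expect_error(null_test(1, numeric(0)), "no null replicates")
})

test_that("null p-values are approximately uniform over repeated experiments", {
  set.seed(6)
  ps <- replicate(400, {
    obs <- rnorm(1)
    null_test(obs, rnorm(39))
  })
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  expect_gt(mean(ps < 0.25), 0.17)
  expect_lt(mean(ps < 0.25), 0.33)
})

test_that("bias curves summarize replicates independently of their order", {
  res <- female_proportion_experiment(bundled_profile("recall_biased"),
                                      n_samples = 400, seed = 3)
  bc1 <- bias_curve(res)
  shuffled <- res[sample(nrow(res)), ]
  class(shuffled) <- class(res)
  bc2 <- bias_curve(shuffled)
  expect_equal(bc1, bc2)
  expect_true(all(bc1$n > 0))
  expect_true(all(bc1$lo10 <= bc1$hi90, na.rm = TRUE))
})
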