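test_that("split R-hat distinguishes mixed from disagreeing chains", {
  set.seed(31)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(split_rhat(good) - 1), 0.02)
  bad <- good
  bad[, 1] <- bad[, 1] + 3
  expect_gt(split_rhat(bad), 1.5)
  # within-chain trend is detected by the split
  trend <- matrix(rnorm(2000), 1000, 2) + seq(0, 3, length.out = 1000)
  expect_gt(split_rhat(trend), 1.2)
})

test_that("effective sample size reflects autocorrelation", {
  set.seed(32)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_gt(ess_basic(iid), 2500)
  ar <- sapply(1:4, function(i) as.numeric(arima.sim(list(ar = 0.9), 1000)))
  expect_lt(ess_basic(ar), 1000)
})

test_that("posterior containers summarize and slice consistently", {
  set.seed(33)
  chains <- lapply(1:3, function(i) cbind(rnorm(500, 2, 1), rgamma(500, 4, 2)))
  fit <- vocalib:::new_posterior_samples(chains, c("a", "b"), model = "toy")
  s <- summary(fit)
  expect_equal(s$param, c("a", "b"))
  expect_equal(s$mean[1], mean(posterior_draws(fit, "a")))
  ci <- posterior_interval(fit, "a", 0.9)
  expect_equal(unname(ci),
               unname(quantile(posterior_draws(fit, "a"), c(0.05, 0.95))))
  expect_equal(posterior_interval(fit, "a", 1), range(posterior_draws(fit, "a")))
  expect_error(posterior_draws(fit, "zzz"), "unknown parameter")
})
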