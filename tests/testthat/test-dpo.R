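test_that("double Poisson reduces exactly to Poisson at tau = 1", {
  for (m in c(0.3, 2, 7, 20)) {
    expect_lt(max(abs(ddpo(0:60, m, 1) - dpois(0:60, m))), 1e-10)
  }
  expect_equal(ddpo(0, 2, 1), exp(-2), tolerance = 1e-12)
})

test_that("renormalized pmf sums to one across dispersion regimes", {
  for (tau in c(0.3, 0.5, 1, 1.5, 3)) {
    for (m in c(0.5, 3, 12)) {
      expect_lt(abs(sum(ddpo(0:400, m, tau)) - 1), 1e-10)
    }
  }
  # large-mean path (analytic normalizer)
  expect_lt(abs(sum(ddpo(0:6000, 3000, 0.7)) - 1), 1e-6)
})

test_that("zero mean gives a point mass at zero", {
  expect_equal(ddpo(0, 0, 0.5), 1)
  expect_equal(ddpo(1:5, 0, 0.5), rep(0, 5))
  expect_equal(rdpo(20, 0, 2), rep(0L, 20))
})

test_that("invalid parameters are rejected", {
  expect_error(ddpo(1, -1, 1), "non-negative")
  expect_error(ddpo(1, 2, 0), "positive")
  expect_error(rdpo(5, 3, -1), "positive")
})

test_that("sampler moments match the distribution's exact moments", {
  set.seed(101)
  cases <- list(c(5, 0.5), c(10, 0.5), c(5, 1.5), c(3, 1))
  for (case in cases) {
    m <- case[1]; tau <- case[2]
    ex <- dpo_exact_moments(m, tau)
    x <- rdpo(2e4, m, tau)
    se_mean <- sqrt(ex$var / length(x))
    expect_lt(abs(mean(x) - ex$mean), 4 * se_mean)
    se_var <- ex$var * sqrt(2 / length(x))
    expect_lt(abs(var(x) - ex$var), 5 * se_var)
  }
})

test_that("exact moments approximate the nominal mean m and variance m/tau", {
  for (case in list(c(5, 0.5), c(10, 0.5), c(5, 0.7), c(8, 1), c(5, 1.5))) {
    ex <- dpo_exact_moments(case[1], case[2])
    expect_lt(abs(ex$mean - case[1]) / case[1], 0.01)
    expect_lt(abs(ex$var - case[1] / case[2]) / (case[1] / case[2]), 0.025)
  }
})

test_that("rdpo is reproducible under a fixed seed", {
  set.seed(7)
  a <- rdpo(50, 4, 0.8)
  set.seed(7)
  b <- rdpo(50, 4, 0.8)
  expect_identical(a, b)
})
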