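test_that("confusion_profile validates its invariants", {
  expect_error(confusion_profile(matrix(-0.1, 4, 4), matrix(2, 4, 4), 1), "non-negative")
  expect_error(confusion_profile(matrix(0.5, 4, 4), matrix(0.5, 4, 4), 1), ">= 1")
  expect_error(confusion_profile(matrix(0.5, 4, 4), matrix(2, 4, 4), 0), "positive")
  p <- bundled_profile("precision_biased")
  expect_s3_class(p, "confusion_profile")
  expect_true(all(p$mu >= 0), all(p$alpha >= 1))
})

test_that("sample_confusion draws have the profile's means and concentrate for large shapes", {
  p <- confusion_profile(mu = test_lambda(), alpha = matrix(4, 4, 4), tau = 1)
  set.seed(42)
  draws <- sample_confusion(p, n = 2e4)
  emp <- apply(draws, c(1, 2), mean)
  # Gamma(shape a, mean mu): SD of the cell mean = mu / sqrt(a n)
  se <- p$mu / sqrt(4 * 2e4)
  expect_true(all(abs(emp - p$mu) < 5 * se))
  expect_true(all(draws >= 0))

  concentrated <- confusion_profile(mu = test_lambda(),
                                    alpha = matrix(1e6, 4, 4), tau = 1)
  set.seed(1)
  d2 <- sample_confusion(concentrated, n = 200)
  sds <- apply(d2, c(1, 2), sd)
  expect_true(all(sds < 1e-2 * p$mu))

  set.seed(9); a <- sample_confusion(p)
  set.seed(9); b <- sample_confusion(p)
  expect_identical(a, b)
})

test_that("simulate_counts respects degenerate and near-degenerate limits", {
  lam <- test_lambda()
  set.seed(3)
  expect_equal(unname(simulate_counts(c(0, 0, 0, 0), lam, 0.5)), rep(0L, 4))
  # identity rates with near-degenerate noise reproduce the input
  set.seed(4)
  hits <- replicate(200, all(simulate_counts(c(5, 0, 2, 1), diag(4), 1e3) ==
                               c(5, 0, 2, 1)))
  expect_gt(mean(hits), 0.9)
})

test_that("simulate_counts means follow the linear confusion model", {
  lam <- test_lambda()
  v <- c(4, 1, 3, 2)
  set.seed(11)
  reps <- t(replicate(2e4, simulate_counts(v, lam, 0.7)))
  # exact cell-wise means of the count-noise law (summed per target class)
  exact <- sapply(1:4, function(j) {
    sum(sapply(1:4, function(i) {
      mij <- lam[i, j] * v[i]
      if (mij == 0) 0 else dpo_exact_moments(mij, 0.7)$mean
    }))
  })
  linear <- as.vector(t(lam) %*% v)
  se <- sqrt(linear / 0.7 / nrow(reps))
  expect_true(all(abs(colMeans(reps) - exact) < 4 * se))

  # at tau = 1 the count law is exactly Poisson, where linearity of the
  # class means in lambda' v is exact
  set.seed(12)
  reps1 <- t(replicate(2e4, simulate_counts(v, lam, 1)))
  se1 <- sqrt(linear / nrow(reps1))
  expect_true(all(abs(colMeans(reps1) - linear) < 4 * se1))
})

test_that("window likelihood equals brute-force enumeration over decompositions", {
  lam <- test_lambda()
  cases <- list(
    list(n = c(2, 1, 3, 1), v = c(3, 1, 2, 0), tau = 0.7),
    list(n = c(1, 0, 0, 0), v = c(1, 0, 1, 0), tau = 1),
    list(n = c(0, 0, 0, 0), v = c(2, 2, 2, 2), tau = 0.5),
    list(n = c(4, 2, 1, 0), v = c(2, 3, 1, 1), tau = 1.3)
  )
  for (cs in cases) {
    expect_equal(clip_log_likelihood(cs$n, cs$v, lam, cs$tau),
                 enum_clip_loglik(cs$n, cs$v, lam, cs$tau),
                 tolerance = 1e-10)
  }
})

test_that("window likelihood is a normalized distribution over observed counts", {
  lam <- test_lambda()
  v <- c(1, 0, 1, 1)
  tot <- 0
  for (n1 in 0:14) for (n2 in 0:9) for (n3 in 0:14) for (n4 in 0:11) {
    tot <- tot + exp(clip_log_likelihood(c(n1, n2, n3, n4), v, lam, 0.8))
  }
  expect_lt(abs(tot - 1), 1e-6)
})

test_that("degenerate window likelihood cases behave", {
  expect_equal(clip_log_likelihood(c(0, 0, 0, 0), c(0, 0, 0, 0),
                                   matrix(0, 4, 4), 1), 0)
  expect_error(clip_log_likelihood(c(50, 0, 0, 0), c(1, 0, 0, 0),
                                   test_lambda(), 1), "cap")
})

test_that("window likelihood matches Monte-Carlo frequencies", {
  lam <- test_lambda()
  v <- c(1, 0, 1, 0)
  n <- c(1, 0, 0, 0)
  p_exact <- exp(clip_log_likelihood(n, v, lam, 1))
  set.seed(5)
  hits <- replicate(2e5, all(simulate_counts(v, lam, 1) == n))
  se <- sqrt(p_exact * (1 - p_exact) / length(hits))
  expect_lt(abs(mean(hits) - p_exact), 3 * se)
})

test_that("recording likelihood agrees with the window likelihood in the one-source limit", {
  lam <- diag(4) * 0.7
  v <- c(50, 0, 0, 0)
  for (n1 in c(25, 35, 40)) {
    a <- clip_log_likelihood(c(n1, 0, 0, 0), v, lam, 0.7, cap = 60)
    b <- recording_log_likelihood(c(n1, 0, 0, 0), v, lam, 0.7)
    expect_lt(abs(a - b) / abs(a), 0.02)
  }
})

test_that("recording likelihood is unimodal around its mean", {
  lam <- test_lambda()
  v <- c(10, 4, 8, 2)
  mj <- as.vector(t(lam) %*% v)
  ll <- sapply(0:40, function(n1) {
    recording_log_likelihood(c(n1, round(mj[2]), round(mj[3]), round(mj[4])),
                             v, lam, 0.8)
  })
  mode_idx <- which.max(ll)
  expect_true(all(diff(ll[seq_len(mode_idx)]) > 0))
  expect_true(all(diff(ll[mode_idx:length(ll)]) < 0))
  expect_equal(recording_log_likelihood(c(0, 0, 0, 0), c(0, 0, 0, 0),
                                        lam, 1), 0)
})

test_that("confusion profiles round-trip through their text format", {
  p <- bundled_profile("precision_biased")
  path <- tempfile(fileext = ".txt")
  write_confusion_profile(p, path)
  q <- read_confusion_profile(path)
  expect_equal(p$mu, q$mu)
  expect_equal(p$alpha, q$alpha)
  expect_equal(p$tau, q$tau)
})
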