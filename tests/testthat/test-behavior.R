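test_that("age basis is log-linear to 24 months then flat", {
  expect_equal(age_basis(0), 0)
  expect_equal(age_basis(12), 0.5)
  expect_equal(age_basis(24), 1)
  expect_equal(age_basis(36), 1)
  expect_error(age_basis(-1), "non-negative")
})

test_that("sibling effects act on OCH and adults, never on CHI", {
  par0 <- behavior_params(beta_sib_och = 0, beta_sib_adu = 0)
  ch_none <- child_state(mu_child = log(c(100, 50, 200, 80)), n_siblings = 0)
  ch_two <- child_state(mu_child = log(c(100, 50, 200, 80)), n_siblings = 2)
  expect_equal(expected_rates(par0, ch_none, 10), expected_rates(par0, ch_two, 10))

  par <- behavior_params(beta_sib_och = 1.1, beta_sib_adu = -0.22)
  r_none <- expected_rates(par, ch_none, 10)
  r_two <- expected_rates(par, ch_two, 10)
  expect_equal(r_none[["CHI"]], r_two[["CHI"]])
  expect_equal(r_two[["OCH"]] / r_none[["OCH"]], exp(1.1))
  expect_equal(r_two[["FEM"]] / r_none[["FEM"]], exp(-0.22))
  expect_equal(r_two[["MAL"]] / r_none[["MAL"]], exp(-0.22))
})

test_that("children's output at birth equals their child-level rate", {
  par <- behavior_params()
  for (slope in c(-0.5, 0, 2)) {
    ch <- child_state(mu_child = log(c(100, 50, 200, 80)), alpha_c_dev = slope)
    expect_equal(expected_rates(par, ch, 0)[["CHI"]], 100)
  }
})

test_that("a slope of log 2 doubles child output from birth to the plateau", {
  par <- behavior_params(beta_dev = 0)
  ch <- child_state(mu_child = log(c(100, 50, 200, 80)), alpha_c_dev = log(2))
  r0 <- expected_rates(par, ch, 0)[["CHI"]]
  r24 <- expected_rates(par, ch, 24)[["CHI"]]
  r36 <- expected_rates(par, ch, 36)[["CHI"]]
  expect_equal(r24 / r0, 2)
  expect_equal(r36, r24)
})

test_that("child output increases strictly with the developmental slope", {
  par <- behavior_params(beta_dev = 0)
  rates <- sapply(c(0.2, 0.5, 1, 1.5), function(s) {
    ch <- child_state(mu_child = log(c(100, 50, 200, 80)), alpha_c_dev = s)
    expected_rates(par, ch, 18)[["CHI"]]
  })
  expect_true(all(diff(rates) > 0))
  expect_true(all(rates > 0))
})

test_that("the reference cohort produces 200 x 5 = 1000 recordings", {
  corpus <- simulate_true_counts(behavior_params(), children = 200,
                                 recordings_per_child = 5, seed = 3)
  expect_equal(nrow(corpus), 1000L)
  expect_equal(length(unique(corpus$child_id)), 200L)
  expect_true(all(corpus[, speaker_classes()] >= 0))
})

test_that("simulated counts match the marginal expectation of the GLM", {
  # degenerate hierarchy so the marginal mean is closed-form
  par <- behavior_params(sigma_corpus = 0, sigma_child = 0, sigma_dev = 0,
                         beta_sib_och = 0, beta_sib_adu = 0, beta_dev = 0,
                         alpha_dev = 0, phi = 5)
  corpus <- simulate_true_counts(par, children = 150, recordings_per_child = 4,
                                 seed = 8)
  m_fem <- exp(par$mu_pop[["FEM"]])
  x <- corpus$FEM
  se <- sqrt((m_fem + m_fem^2 / par$phi) / length(x))
  expect_lt(abs(mean(x) - m_fem), 4 * se)
})

test_that("a degenerate hierarchy gives near-identical counts for identical covariates", {
  par <- behavior_params(sigma_corpus = 0, sigma_child = 0, sigma_dev = 0,
                         beta_dev = 0, phi = 1e7)
  children <- tibble::tibble(child_id = c("a", "b"), corpus_id = "c1",
                             n_siblings = 0L, age_base = 10)
  corpus <- simulate_true_counts(par, children, recordings_per_child = 1, seed = 2)
  # with the gamma layer degenerate only Poisson noise remains
  m <- exp(par$mu_pop[["FEM"]])
  expect_true(all(abs(corpus$FEM - m) < 4 * sqrt(m)))
})

test_that("corpus simulation is reproducible under a fixed seed", {
  a <- simulate_true_counts(behavior_params(), 10, 2, seed = 5)
  b <- simulate_true_counts(behavior_params(), 10, 2, seed = 5)
  expect_equal(a, b)
})
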