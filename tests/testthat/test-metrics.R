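test_that("speaker correlation matrix has unit diagonal, symmetry, and exact limits", {
  set.seed(41)
  counts <- tibble::tibble(CHI = rpois(50, 8), OCH = rpois(50, 4),
                           FEM = rpois(50, 10), MAL = rpois(50, 3))
  counts$OCH <- counts$CHI  # duplicated column: perfect correlation
  cr <- pearson_by_speaker_pair(counts, level = "clip")
  expect_equal(diag(cr$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cr$r, t(cr$r))
  expect_equal(cr$r["CHI", "OCH"], 1)
  expect_equal(cr$n, 50)
  td <- tidy_correlations(cr)
  expect_equal(nrow(td), 6L)
  expect_true(all(td$N == 50))
})

test_that("independent counts correlate near zero; shared confusion inflates correlation", {
  set.seed(42)
  n <- 800
  truth <- tibble::tibble(CHI = rpois(n, 6), OCH = rpois(n, 2),
                          FEM = rpois(n, 8), MAL = rpois(n, 3))
  r_true <- pearson_by_speaker_pair(truth, "clip")$r["CHI", "FEM"]
  expect_lt(abs(r_true), 3 / sqrt(n))

  # classifier that leaks FEM vocalizations into CHI
  sp <- speaker_classes()
  mu <- diag(4) * 0.7
  mu[3, 1] <- 0.4  # FEM -> CHI
  leaky <- confusion_profile(mu, matrix(8, 4, 4), tau = 1)
  meas <- apply_classifier(truth, leaky)
  r_meas <- pearson_by_speaker_pair(meas, "clip")$r["CHI", "FEM"]
  expect_gt(r_meas, r_true + 0.1)
})

test_that("constant columns are flagged as NA, not reported as zero", {
  counts <- tibble::tibble(CHI = rpois(30, 5), OCH = rep(2L, 30),
                           FEM = rpois(30, 5), MAL = rpois(30, 5))
  expect_warning(cr <- pearson_by_speaker_pair(counts, "clip"), "constant")
  expect_true(is.na(cr$r["CHI", "OCH"]))
  expect_false(is.na(cr$r["CHI", "FEM"]))
})

test_that("aggregation levels collapse windows to recordings and children", {
  counts <- tibble::tibble(
    recording_id = rep(c("r1", "r2"), each = 3),
    child_id = rep(c("c1", "c2"), each = 3),
    CHI = c(1, 2, 3, 4, 5, 6), OCH = 0L, FEM = c(2, 2, 2, 1, 1, 1), MAL = 1L
  )
  expect_error(pearson_by_speaker_pair(counts, "recording"), "at least 3")
  counts2 <- dplyr::bind_rows(counts, dplyr::mutate(counts,
    recording_id = paste0(recording_id, "b"), child_id = paste0(child_id, "b")))
  cr <- suppressWarnings(pearson_by_speaker_pair(counts2, "recording"))
  expect_equal(cr$n, 4)
})

test_that("ICC(A,1) equals 1 for identity, is symmetric in raters, and matches an aov oracle", {
  expect_equal(icc(1:10, 1:10), 1)
  set.seed(43)
  subj <- rnorm(60, 0, 1)
  x <- subj + rnorm(60, 0, 1)
  y <- subj + rnorm(60, 0, 1)
  expect_equal(icc(x, y), icc(y, x))

  # independent aov-based mean-squares computation (two-way, absolute agreement)
  n <- length(x)
  dat <- data.frame(score = c(x, y),
                    subject = factor(rep(seq_len(n), 2)),
                    rater = factor(rep(1:2, each = n)))
  ms <- anova(aov(score ~ subject + rater, data = dat))
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  oracle <- (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
  expect_equal(icc(x, y), oracle, tolerance = 1e-10)
})

test_that("ICC recovers its generative value and vanishes for independent pairs", {
  set.seed(44)
  n <- 4000
  subj <- rnorm(n, 0, 1)              # variance split 1:1 -> true ICC = 0.5
  x <- subj + rnorm(n, 0, 1)
  y <- subj + rnorm(n, 0, 1)
  expect_lt(abs(icc(x, y) - 0.5), 0.05)
  expect_lt(abs(icc(rnorm(n), rnorm(n))), 0.05)
})

test_that("female adult proportion follows its definition and flags emptiness", {
  expect_equal(female_adult_proportion(c(FEM = 3000, MAL = 0)), 1)
  expect_equal(female_adult_proportion(c(FEM = 500, MAL = 500)), 0.5)
  expect_equal(female_adult_proportion(c(FEM = 3000 * 0.3, MAL = 3000 * 0.7)), 0.3)
  expect_warning(p <- female_adult_proportion(c(FEM = 0, MAL = 0)), "undefined")
  expect_true(is.na(p))
})
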