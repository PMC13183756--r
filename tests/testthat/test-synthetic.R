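test_that("calibration clip fixtures have the requested shape and reproduce exactly", {
  spec <- fixture_spec(calib_recordings = 10, windows_per_recording = 8, seed = 3)
  clips <- make_calibration_clips(spec)
  expect_equal(nrow(clips), 80L)
  expect_equal(length(unique(clips$recording_id)), 10L)
  expect_true(all(clips[, grep("^[vn]_", names(clips))] >= 0))
  clips2 <- make_calibration_clips(spec)
  expect_equal(clips, clips2)
})

test_that("aggregate clip confusion frequencies recover the profile means", {
  prof <- confusion_profile(mu = test_lambda(), alpha = matrix(50, 4, 4), tau = 1)
  spec <- fixture_spec(calib_recordings = 40, windows_per_recording = 40,
                       profile = prof,
                       window_rates = c(CHI = 2, OCH = 1, FEM = 2, MAL = 1),
                       seed = 10)
  clips <- make_calibration_clips(spec)
  vbar <- colMeans(clips[, paste0("v_", speaker_classes())])
  nbar <- colMeans(clips[, paste0("n_", speaker_classes())])
  expected <- as.vector(t(prof$mu) %*% vbar)
  expect_true(all(abs(nbar - expected) / expected < 0.08))
})

test_that("synthetic corpora are complete, consistent and loader-clean", {
  spec <- fixture_spec(n_children = 8, recordings_per_child = 2,
                       calib_recordings = 4, windows_per_recording = 6, seed = 6)
  dir <- tempfile()
  corp <- make_corpus(spec, dir = dir)
  expect_equal(nrow(corp$recordings), 16L)
  expect_identical(corp$recordings$recording_id, corp$truth$recording_id)
  meta <- read_metadata(corp$files[["metadata"]])
  expect_equal(nrow(meta), 16L)
  counts <- utils::read.csv(corp$files[["counts"]])
  expect_identical(sort(meta$recording_id), sort(counts$recording_id))
  # the written dataset feeds the fitting interface without warnings
  recordings <- dplyr::inner_join(meta, tibble::as_tibble(counts),
                                  by = "recording_id")
  expect_no_warning(vocalib:::joint_data(recordings))
})

test_that("a negative adult sibling effect lowers sibling children's true adult counts", {
  par <- behavior_params(beta_sib_adu = -0.8, sigma_corpus = 0, sigma_child = 0.05)
  corpus <- simulate_true_counts(par, 120, 2, seed = 12)
  adults <- corpus$FEM + corpus$MAL
  m_sib <- mean(adults[corpus$n_siblings > 0])
  m_none <- mean(adults[corpus$n_siblings == 0])
  expect_lt(m_sib, m_none)
})
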