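test_that("CSV segments parse with millisecond conversion", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("recording_id,annotator_id,speaker_type,segment_onset,segment_offset",
               "rec1,human,FEM,1000,2500"), path)
  segs <- read_segments(path)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$onset, 1.0)
  expect_equal(segs$offset, 2.5)
  expect_equal(segs$speaker, "FEM")
})

test_that("empty CSV with header yields an empty collection", {
  path <- tempfile(fileext = ".csv")
  writeLines("recording_id,annotator_id,speaker_type,segment_onset,segment_offset", path)
  segs <- read_segments(path)
  expect_equal(nrow(segs), 0L)
  expect_true(all(c("recording_id", "annotator_id", "speaker", "onset",
                    "offset") %in% names(segs)))
})

test_that("malformed rows raise errors naming the line", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("recording_id,annotator_id,speaker_type,segment_onset,segment_offset",
               "rec1,human,FEM,1000,2500",
               "rec1,human,CHI,3000,2000"), path)
  expect_error(read_segments(path), "line 3")

  rttm <- tempfile(fileext = ".rttm")
  writeLines(c("SPEAKER rec1 1 4.000 1.500 <NA> <NA> CHI <NA> <NA>",
               "SPEAKER rec1 1 6.000 -1.000 <NA> <NA> FEM <NA> <NA>"), rttm)
  expect_error(read_segments(rttm), "line 2")
  expect_error(read_segments(tempfile(), format = "csv"), "no such file")
})

test_that("unknown speaker labels are dropped with a reported count", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("recording_id,annotator_id,speaker_type,segment_onset,segment_offset",
               "rec1,human,FEM,0,400",
               "rec1,human,TVN,500,900",
               "rec1,human,ELE,1000,1200"), path)
  expect_message(segs <- read_segments(path), "2 segment")
  expect_equal(nrow(segs), 1L)
})

test_that("segment tables round-trip through CSV and RTTM", {
  segs <- make_segments("recA", c("CHI", "FEM", "MAL"),
                        onset = c(0.25, 3.5, 10), offset = c(1.25, 5, 12.5))
  for (fmt in c("csv", "rttm")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_segments(segs, path, format = fmt)
    back <- read_segments(path, annotator = "human")
    expect_equal(back$recording_id, segs$recording_id)
    expect_equal(back$speaker, segs$speaker)
    expect_equal(back$onset, segs$onset, tolerance = 1e-9)
    expect_equal(back$offset, segs$offset, tolerance = 1e-9)
    # idempotence: a second round trip is exact
    path2 <- tempfile(fileext = paste0(".", fmt))
    write_segments(back, path2, format = fmt)
    again <- read_segments(path2, annotator = "human")
    expect_equal(again, back)
  }
})

test_that("time-of-day filter keeps the half-open daytime interval", {
  # recording starts at 09:00; onsets at clock 09:59, 10:00, 17:59, 18:00
  segs <- make_segments("rec1", rep("FEM", 4),
                        onset = c(3540, 3600, 32340, 32400),
                        offset = c(3541, 3601, 32341, 32401))
  kept <- filter_time_of_day(segs, c(rec1 = "09:00"))
  expect_equal(kept$onset, c(3600, 32340))
  expect_error(filter_time_of_day(segs, c(other = "09:00")), "rec1")
})

test_that("a two-minute clip yields eight 15-s windows", {
  segs <- make_segments("rec1", "CHI", onset = 5, offset = 6)
  cb <- data.frame(clip_id = "c1", recording_id = "rec1", onset = 0, offset = 120)
  wc <- window_counts(segs, cb)
  expect_equal(nrow(wc), 8L)
  expect_equal(sort(unique(wc$window_index)), 0:7)
  # empty windows carry zero counts
  expect_equal(sum(wc$CHI), 1L)
  expect_true(all(rowSums(wc[wc$window_index > 0, speaker_classes()]) == 0))
})

test_that("vocalizations belong to the window containing their onset", {
  segs <- make_segments("rec1", c("FEM", "FEM", "FEM", "CHI"),
                        onset = c(1, 5, 12, 14.9),
                        offset = c(2, 6, 13, 16.2))  # CHI straddles 15 s
  cb <- data.frame(clip_id = "c1", recording_id = "rec1", onset = 0, offset = 30)
  wc <- window_counts(segs, cb)
  w0 <- wc[wc$window_index == 0, ]
  expect_equal(w0$FEM, 3L)
  expect_equal(w0$CHI, 1L)
  expect_equal(wc[wc$window_index == 1, ]$CHI, 0L)
})

test_that("clips must be multiples of the window length", {
  segs <- make_segments("rec1", "CHI", 1, 2)
  cb <- data.frame(clip_id = "bad", recording_id = "rec1", onset = 0, offset = 100)
  expect_error(window_counts(segs, cb), "multiple")
})

test_that("window counts sum to clip totals and ignore segment order", {
  set.seed(21)
  n <- 40
  segs <- make_segments("rec1", sample(speaker_classes(), n, replace = TRUE),
                        onset = runif(n, 0, 60), offset = runif(n, 60, 70))
  cb <- data.frame(clip_id = "c1", recording_id = "rec1", onset = 0, offset = 60)
  wc <- window_counts(segs, cb)
  totals <- colSums(wc[, speaker_classes()])
  expect_equal(unname(totals), unname(table(factor(segs$speaker,
                                                   speaker_classes()))[speaker_classes()]),
               ignore_attr = TRUE)
  shuffled <- segs[sample(n), ]
  wc2 <- window_counts(shuffled, cb)
  expect_equal(wc, wc2)
})

test_that("recording counts tally per annotator and add across subsets", {
  segs <- make_segments("rec1", c("FEM", "FEM", "CHI"), 1:3, 4:6)
  rc <- recording_counts(segs)
  expect_equal(rc$FEM, 2L)
  expect_equal(rc$CHI, 1L)
  expect_equal(nrow(recording_counts(segs[0, ])), 0L)
  # additivity over a concatenation of two recordings
  segs2 <- make_segments("rec2", c("FEM", "MAL"), 1:2, 3:4)
  both <- recording_counts(rbind(segs, segs2))
  expect_equal(sum(both$FEM), 3L)
  expect_equal(sum(both$MAL), 1L)
})

test_that("calibration_clips pairs truth and classifier windows", {
  segs <- rbind(
    make_segments("rec1", c("CHI", "FEM"), c(1, 16), c(2, 18), "human"),
    make_segments("rec1", c("CHI", "CHI", "FEM"), c(1, 16, 16.5),
                  c(2, 17, 18), "vtc_like")
  )
  cb <- data.frame(clip_id = "c1", recording_id = "rec1", onset = 0, offset = 30)
  wc <- window_counts(segs, cb)
  clips <- calibration_clips(wc, truth = "human", classifier = "vtc_like")
  expect_equal(nrow(clips), 2L)
  expect_equal(clips$v_CHI, c(1L, 0L))
  expect_equal(clips$n_CHI, c(1L, 1L))
  expect_equal(clips$n_FEM, c(0L, 1L))
  expect_error(calibration_clips(wc, truth = "nobody", classifier = "vtc_like"),
               "nobody")
})
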