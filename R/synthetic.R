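#' Simulate classifier output for recording-level counts
#'
#' Applies the confusion model to a table of true recording-level counts:
#' for each recording, recording-specific confusion rates are drawn from the
#' profile and classifier counts are simulated with double-Poisson noise
#' (see [simulate_counts()]). Uses R's RNG; call `set.seed()` for
#' reproducibility.
#'
#' @param recordings a tibble with true counts in columns `CHI`, `OCH`,
#'   `FEM`, `MAL` (e.g. from [simulate_true_counts()]).
#' @param profile a [confusion_profile()].
#' @return The same tibble with the count columns replaced by simulated
#'   classifier counts.
#' @export
apply_classifier <- function(recordings, profile) {
  sp <- speaker_classes()
  out <- recordings
  for (r in seq_len(nrow(recordings))) {
    lam <- sample_confusion(profile)
    v <- as.integer(unlist(recordings[r, sp]))
    n <- simulate_counts(v, lam, profile$tau)
    out[r, sp] <- as.list(as.integer(n))
  }
  out
}

#' Specification of a synthetic fixture
#'
#' Collects the sizes, behavior parameters and confusion profile used by
#' the synthetic-data generators, so that every module of the package can
#' be exercised without any external data.
#'
#' @param n_children,recordings_per_child cohort size for [make_corpus()].
#' @param calib_recordings,windows_per_recording size of the calibration
#'   clip set for [make_calibration_clips()].
#' @param params a [behavior_params()].
#' @param profile a [confusion_profile()].
#' @param window_rates length-4 vector of mean true counts per 15-s window
#'   (Poisson law) used for calibration clips.
#' @param classifier name given to the simulated classifier.
#' @param seed integer seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_children = 20, recordings_per_child = 3,
                         calib_recordings = 10, windows_per_recording = 8,
                         params = behavior_params(),
                         profile = bundled_profile("recall_biased"),
                         window_rates = c(CHI = 1.5, OCH = 0.5, FEM = 1.2, MAL = 0.4),
                         classifier = "synthetic_classifier", seed = 1) {
  stopifnot(n_children >= 1, recordings_per_child >= 1,
            calib_recordings >= 1, windows_per_recording >= 1)
  structure(list(n_children = n_children,
                 recordings_per_child = recordings_per_child,
                 calib_recordings = calib_recordings,
                 windows_per_recording = windows_per_recording,
                 params = params, profile = profile,
                 window_rates = as_count4(window_rates, "window_rates"),
                 classifier = classifier, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate synthetic calibration clips
#'
#' Simulates human-annotated 15-s windows: true window counts are Poisson
#' with the spec's window rates, recording-specific confusion rates are
#' drawn from the profile, and classifier counts follow the double-Poisson
#' confusion model. Both true and classifier counts are returned, ready for
#' [fit_confusion()].
#'
#' @param spec a [fixture_spec()].
#' @return A calibration tibble (`recording_id`, `clip_id`, `window_index`,
#'   `v_*`, `n_*`), as produced by [calibration_clips()].
#' @export
make_calibration_clips <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  sp <- speaker_classes()
  rows <- list()
  q <- 0L
  for (k in seq_len(spec$calib_recordings)) {
    lam <- sample_confusion(spec$profile)
    for (w in seq_len(spec$windows_per_recording)) {
      v <- rpois(4, spec$window_rates)
      n <- simulate_counts(v, lam, spec$profile$tau)
      q <- q + 1L
      rows[[q]] <- tibble::tibble(
        recording_id = sprintf("calib%03d", k),
        clip_id = sprintf("calib%03d_clip", k),
        window_index = w - 1L,
        v_CHI = v[1], v_OCH = v[2], v_FEM = v[3], v_MAL = v[4],
        n_CHI = n[["CHI"]], n_OCH = n[["OCH"]],
        n_FEM = n[["FEM"]], n_MAL = n[["MAL"]]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "classifier") <- spec$classifier
  out
}

#' Generate a full synthetic corpus
#'
#' End-to-end synthetic dataset: true recording-level counts from the
#' behavior model, classifier counts from the confusion model, and a
#' matching set of calibration clips. Optionally written to disk as
#' plain-text CSV (metadata, classifier counts, calibration clips) with the
#' truth kept in a sidecar file for scoring.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory.
#' @return A list with elements `recordings` (classifier counts plus
#'   metadata, the analysis input), `truth` (the same rows with true
#'   counts), `clips` (calibration table) and, when `dir` is given,
#'   `files` (paths written).
#' @export
make_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  truth <- simulate_true_counts(spec$params, spec$n_children,
                                spec$recordings_per_child, seed = spec$seed)
  set.seed(spec$seed + 1L)
  meas <- apply_classifier(truth, spec$profile)
  clips <- make_calibration_clips(fixture_spec(
    calib_recordings = spec$calib_recordings,
    windows_per_recording = spec$windows_per_recording,
    params = spec$params, profile = spec$profile,
    window_rates = spec$window_rates, classifier = spec$classifier,
    seed = spec$seed + 2L))
  out <- list(recordings = meas, truth = truth, clips = clips)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sp <- speaker_classes()
    meta_cols <- c("recording_id", "child_id", "corpus_id", "age_months",
                   "n_siblings")
    files <- c(
      metadata = file.path(dir, "metadata.csv"),
      counts = file.path(dir, paste0("counts_", spec$classifier, ".csv")),
      truth = file.path(dir, "counts_true_sidecar.csv"),
      clips = file.path(dir, "calibration_clips.csv")
    )
    utils::write.csv(meas[, meta_cols], files["metadata"], row.names = FALSE)
    utils::write.csv(meas[, c("recording_id", sp)], files["counts"],
                     row.names = FALSE)
    utils::write.csv(truth[, c("recording_id", sp)], files["truth"],
                     row.names = FALSE)
    utils::write.csv(clips, files["clips"], row.names = FALSE)
    out$files <- files
  }
  out
}
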