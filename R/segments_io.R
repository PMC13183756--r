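#' Read diarization segment tables
#'
#' Reads speech segments ("vocalizations") from either a standard RTTM file
#' (`SPEAKER` records, times in seconds) or a CSV table with columns
#' `recording_id`, `speaker_type`, `segment_onset`, `segment_offset`
#' (onset/offset in integer milliseconds) and optionally `annotator_id`.
#' Segments whose speaker label is not one of CHI, OCH, FEM, MAL (e.g.
#' electronic noise) are dropped, and the number of dropped rows is reported
#' with a message.
#'
#' @param path path to the file.
#' @param format `"auto"` (by extension), `"rttm"` or `"csv"`.
#' @param annotator annotator id to assign when the file carries none
#'   (RTTM, or CSV without an `annotator_id` column).
#' @return A tibble with columns `recording_id`, `annotator_id`, `speaker`,
#'   `onset`, `offset` (seconds from recording start).
#' @export
read_segments <- function(path, format = c("auto", "rttm", "csv"),
                          annotator = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, rttm = "rttm", csv = "csv",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format = \"rttm\" or \"csv\""))
  }
  segs <- switch(format,
                 rttm = read_rttm(path, annotator),
                 csv = read_segments_csv(path, annotator))
  known <- segs$speaker %in% speaker_classes()
  if (any(!known)) {
    message(sum(!known), " segment(s) with speaker labels outside ",
            "{CHI, OCH, FEM, MAL} dropped")
    segs <- segs[known, , drop = FALSE]
  }
  tibble::as_tibble(segs)
}

read_rttm <- function(path, annotator) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  out <- vector("list", length(keep))
  for (t in seq_along(keep)) {
    ln <- keep[t]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 8L || f[1] != "SPEAKER") {
      stop("malformed RTTM line ", ln, " in ", path)
    }
    tbeg <- suppressWarnings(as.numeric(f[4]))
    tdur <- suppressWarnings(as.numeric(f[5]))
    if (is.na(tbeg) || is.na(tdur) || tbeg < 0 || tdur <= 0) {
      stop("malformed RTTM line ", ln, " in ", path,
           ": need onset >= 0 and duration > 0")
    }
    out[[t]] <- data.frame(recording_id = f[2], annotator_id = annotator,
                           speaker = f[8], onset = tbeg, offset = tbeg + tdur,
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(recording_id = character(), annotator_id = character(),
                      speaker = character(), onset = numeric(),
                      offset = numeric()))
  }
  do.call(rbind, out)
}

read_segments_csv <- function(path, annotator) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "speaker_type", "segment_onset", "segment_offset")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("CSV ", path, " is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!nrow(tab)) {
    return(data.frame(recording_id = character(), annotator_id = character(),
                      speaker = character(), onset = numeric(),
                      offset = numeric()))
  }
  on <- suppressWarnings(as.numeric(tab$segment_onset))
  off <- suppressWarnings(as.numeric(tab$segment_offset))
  bad <- which(is.na(on) | is.na(off) | on < 0 | off <= on)
  if (length(bad)) {
    stop("malformed segment at line ", bad[1] + 1L, " of ", path,
         ": need 0 <= onset < offset in milliseconds")
  }
  data.frame(
    recording_id = as.character(tab$recording_id),
    annotator_id = if ("annotator_id" %in% names(tab))
      as.character(tab$annotator_id) else annotator,
    speaker = as.character(tab$speaker_type),
    onset = on / 1000, offset = off / 1000,
    stringsAsFactors = FALSE
  )
}

#' Write a segment table
#'
#' Inverse of [read_segments()]: writes CSV (integer milliseconds) or RTTM
#' (seconds). Round-trips through `read_segments` preserve all fields.
#'
#' @param segments a segment tibble as returned by [read_segments()].
#' @param path output file path.
#' @param format `"csv"` or `"rttm"`.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, format = c("csv", "rttm")) {
  format <- match.arg(format)
  if (format == "csv") {
    out <- data.frame(
      recording_id = segments$recording_id,
      annotator_id = segments$annotator_id,
      speaker_type = segments$speaker,
      segment_onset = as.integer(round(segments$onset * 1000)),
      segment_offset = as.integer(round(segments$offset * 1000))
    )
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- sprintf("SPEAKER %s 1 %.3f %.3f <NA> <NA> %s <NA> <NA>",
                     segments$recording_id, segments$onset,
                     segments$offset - segments$onset, segments$speaker)
    writeLines(lines, path)
  }
  invisible(path)
}

parse_clock <- function(x) {
  ok <- grepl("^\\d{1,2}:\\d{2}$", x)
  if (any(!ok)) stop("invalid clock time(s): ", paste(x[!ok], collapse = ", "),
                     " (expected HH:MM)")
  h <- as.numeric(sub(":.*", "", x))
  m <- as.numeric(sub(".*:", "", x))
  setNames(3600 * h + 60 * m, names(x))
}

#' Restrict segments to a daytime window
#'
#' Keeps only segments whose onset clock time falls inside `[lo, hi)` (a
#' half-open interval; by default 10:00 to 18:00), given the wall-clock
#' start time of each recording.
#'
#' @param segments a segment tibble (see [read_segments()]).
#' @param recording_start_clock either a named character vector mapping
#'   recording ids to "HH:MM" start times, or a data frame with columns
#'   `recording_id` and `start_clock`.
#' @param lo,hi clock bounds as "HH:MM".
#' @return The filtered segment tibble.
#' @export
filter_time_of_day <- function(segments, recording_start_clock,
                               lo = "10:00", hi = "18:00") {
  if (is.data.frame(recording_start_clock)) {
    starts <- setNames(recording_start_clock$start_clock,
                       recording_start_clock$recording_id)
  } else starts <- recording_start_clock
  missing_ids <- setdiff(unique(segments$recording_id), names(starts))
  if (length(missing_ids)) {
    stop("missing start clock time for recording(s): ",
         paste(missing_ids, collapse = ", "))
  }
  start_s <- parse_clock(starts)[segments$recording_id]
  clock <- start_s + segments$onset
  segments[clock >= parse_clock(lo) & clock < parse_clock(hi), , drop = FALSE]
}

#' Count vocalizations in fixed windows of annotated clips
#'
#' Splits each annotated clip into consecutive windows of `window_s` seconds
#' and counts, per annotator and speaker class, the vocalizations whose
#' onset falls inside each window (a vocalization belongs to the window
#' containing its onset; this rule avoids double counting and is independent
#' of segment order). Clip durations must be multiples of `window_s`.
#'
#' @param segments a segment tibble (see [read_segments()]). Onsets are
#'   relative to the recording start.
#' @param clip_bounds data frame with columns `clip_id`, `recording_id`,
#'   `onset`, `offset` (seconds).
#' @param window_s window length in seconds (default 15).
#' @return A tibble with one row per clip window and annotator: `clip_id`,
#'   `recording_id`, `window_index` (0-based), `annotator_id`, and count
#'   columns `CHI`, `OCH`, `FEM`, `MAL`. Windows without segments appear
#'   with zero counts.
#' @export
window_counts <- function(segments, clip_bounds, window_s = 15) {
  sp <- speaker_classes()
  durs <- clip_bounds$offset - clip_bounds$onset
  bad <- which(abs(durs / window_s - round(durs / window_s)) > 1e-9 | durs <= 0)
  if (length(bad)) {
    stop("clip duration must be a positive multiple of ", window_s,
         " s; offending clip(s): ",
         paste(clip_bounds$clip_id[bad], collapse = ", "))
  }
  annotators <- sort(unique(segments$annotator_id))
  if (!length(annotators)) annotators <- "unknown"
  out <- list()
  for (r in seq_len(nrow(clip_bounds))) {
    cb <- clip_bounds[r, ]
    n_win <- as.integer(round((cb$offset - cb$onset) / window_s))
    grid <- expand.grid(window_index = seq_len(n_win) - 1L,
                        annotator_id = annotators,
                        stringsAsFactors = FALSE)
    counts <- matrix(0L, nrow(grid), 4, dimnames = list(NULL, sp))
    segs <- segments[segments$recording_id == cb$recording_id &
                       segments$onset >= cb$onset &
                       segments$onset < cb$offset, , drop = FALSE]
    if (nrow(segs)) {
      w <- floor((segs$onset - cb$onset) / window_s)
      for (q in seq_len(nrow(segs))) {
        row <- which(grid$window_index == w[q] &
                       grid$annotator_id == segs$annotator_id[q])
        counts[row, segs$speaker[q]] <- counts[row, segs$speaker[q]] + 1L
      }
    }
    out[[r]] <- tibble::tibble(
      clip_id = cb$clip_id, recording_id = cb$recording_id,
      window_index = grid$window_index, annotator_id = grid$annotator_id,
      CHI = counts[, "CHI"], OCH = counts[, "OCH"],
      FEM = counts[, "FEM"], MAL = counts[, "MAL"]
    )
  }
  dplyr::bind_rows(out)
}

#' Count vocalizations per recording
#'
#' Tallies the number of segments per recording, annotator and speaker
#' class. Counts are additive across subsets of segments and invariant to
#' segment order.
#'
#' @param segments a segment tibble (see [read_segments()]).
#' @return A tibble with columns `recording_id`, `annotator_id`, `CHI`,
#'   `OCH`, `FEM`, `MAL`.
#' @export
recording_counts <- function(segments) {
  sp <- speaker_classes()
  if (!nrow(segments)) {
    return(tibble::tibble(recording_id = character(),
                          annotator_id = character(),
                          CHI = integer(), OCH = integer(),
                          FEM = integer(), MAL = integer()))
  }
  segments$speaker <- factor(segments$speaker, levels = sp)
  tab <- as.data.frame(table(recording_id = segments$recording_id,
                             annotator_id = segments$annotator_id,
                             speaker = segments$speaker))
  wide <- tidyr::pivot_wider(tab, names_from = "speaker",
                             values_from = "Freq", values_fill = 0L)
  wide$recording_id <- as.character(wide$recording_id)
  wide$annotator_id <- as.character(wide$annotator_id)
  for (s in sp) wide[[s]] <- as.integer(wide[[s]])
  tibble::as_tibble(wide[, c("recording_id", "annotator_id", sp)])
}

#' Pair true and classifier window counts into a calibration table
#'
#' Combines the window counts of a designated ground-truth annotator
#' (typically a human) with those of one classifier into the paired table
#' used to fit the confusion model: columns `v_*` hold the true counts and
#' `n_*` the classifier counts for the same window.
#'
#' @param windows output of [window_counts()].
#' @param truth annotator id providing the ground-truth counts.
#' @param classifier annotator id of the classifier.
#' @return A tibble with columns `clip_id`, `recording_id`, `window_index`,
#'   `v_CHI` ... `v_MAL`, `n_CHI` ... `n_MAL`, carrying the classifier name
#'   as attribute `"classifier"`.
#' @export
calibration_clips <- function(windows, truth, classifier) {
  sp <- speaker_classes()
  for (id in c(truth, classifier)) {
    if (!id %in% windows$annotator_id) {
      stop("annotator '", id, "' not present in the window table")
    }
  }
  tv <- windows[windows$annotator_id == truth, ]
  tn <- windows[windows$annotator_id == classifier, ]
  names(tv)[match(sp, names(tv))] <- paste0("v_", sp)
  names(tn)[match(sp, names(tn))] <- paste0("n_", sp)
  tv$annotator_id <- NULL
  tn$annotator_id <- NULL
  out <- dplyr::inner_join(tv, tn,
                           by = c("clip_id", "recording_id", "window_index"))
  attr(out, "classifier") <- classifier
  out
}

#' Read a recording metadata table
#'
#' Expects a CSV with columns `recording_id`, `child_id`, `corpus_id`,
#' `age_months`, `n_siblings` and optionally `start_clock` ("HH:MM").
#'
#' @param path path to the CSV file.
#' @return A tibble with validated columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "child_id", "corpus_id", "age_months", "n_siblings")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("metadata ", path, " is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(tab$age_months < 0)) stop("age_months must be >= 0")
  if (any(tab$n_siblings < 0)) stop("n_siblings must be >= 0")
  tibble::as_tibble(tab)
}
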