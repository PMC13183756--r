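#' Pairwise correlations between speakers' vocalization counts
#'
#' Pearson correlations between the four speakers' counts across analysis
#' units. The unit is chosen with `level`: `"clip"` uses the rows as given
#' (e.g. 15-s windows), `"recording"` sums window counts within
#' `recording_id`, and `"child"` averages recording-level counts within
#' `child_id`. Speaker confusion inflates these correlations relative to
#' true counts, so comparing the matrix across annotators is a direct probe
#' of classification bias.
#'
#' @param counts tibble with count columns `CHI`, `OCH`, `FEM`, `MAL` and
#'   the id columns required by `level` (`recording_id` and/or `child_id`).
#' @param level aggregation level: `"clip"`, `"recording"` or `"child"`.
#' @return An object of class `speaker_correlations`: a list with 4x4
#'   matrices `r` and `p`, the number of units `n`, and the level.
#'   Correlations undefined because of a constant column are `NA` (with a
#'   warning), never silently zero. `tidy_correlations()` converts the
#'   result to a long tibble.
#' @export
pearson_by_speaker_pair <- function(counts, level = c("clip", "recording", "child")) {
  level <- match.arg(level)
  sp <- speaker_classes()
  if (level %in% c("recording", "child")) {
    if (!"recording_id" %in% names(counts)) {
      stop("level '", level, "' requires a recording_id column")
    }
    counts <- dplyr::summarise(dplyr::group_by(counts, .data$recording_id,
      .add = FALSE),
      child_id = if ("child_id" %in% names(counts)) .data$child_id[1] else NA,
      dplyr::across(dplyr::all_of(sp), sum), .groups = "drop")
  }
  if (level == "child") {
    if (all(is.na(counts$child_id))) stop("level 'child' requires a child_id column")
    counts <- dplyr::summarise(dplyr::group_by(counts, .data$child_id),
                               dplyr::across(dplyr::all_of(sp), mean),
                               .groups = "drop")
  }
  x <- as.matrix(counts[, sp])
  n <- nrow(x)
  if (n < 3) stop("need at least 3 units to correlate")
  r <- p <- matrix(NA_real_, 4, 4, dimnames = list(sp, sp))
  diag(r) <- 1
  diag(p) <- 0
  constant <- apply(x, 2, function(col) sd(col) < 1e-12)
  if (any(constant)) {
    warning("constant count column(s): ", paste(sp[constant], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
  }
  for (i in 1:3) for (j in (i + 1):4) {
    if (constant[i] || constant[j]) next
    ct <- cor.test(x[, i], x[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p, n = n, level = level),
            class = "speaker_correlations")
}

#' @export
print.speaker_correlations <- function(x, ...) {
  cat(sprintf("<speaker_correlations> level = %s, N = %d\n", x$level, x$n))
  print(round(x$r, 3))
  invisible(x)
}

#' @rdname pearson_by_speaker_pair
#' @param corr a `speaker_correlations` object.
#' @export
tidy_correlations <- function(corr) {
  sp <- speaker_classes()
  grid <- expand.grid(speaker_i = sp, speaker_j = sp, stringsAsFactors = FALSE)
  grid <- grid[match(grid$speaker_i, sp) < match(grid$speaker_j, sp), ]
  tibble::tibble(speaker_i = grid$speaker_i, speaker_j = grid$speaker_j,
                 level = corr$level,
                 R = corr$r[cbind(grid$speaker_i, grid$speaker_j)],
                 p = corr$p[cbind(grid$speaker_i, grid$speaker_j)],
                 N = corr$n)
}

#' Intraclass correlation between two raters' counts
#'
#' Two-way absolute-agreement single-measure intraclass correlation
#' (ICC(A,1)): the agreement between two raters (e.g. a human and a
#' classifier, or a classifier before/after calibration) counting the same
#' units, penalizing both disagreement in ranking and systematic offsets.
#'
#' @param x,y numeric vectors of the two raters' counts on the same units.
#' @return The ICC, in `[-1, 1]`; `NA` (with a warning) if the data are
#'   degenerate.
#' @export
#' @examples
#' icc(1:10, 1:10)      # 1
icc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  dat <- cbind(x, y)
  k <- 2
  grand <- mean(dat)
  si <- rowMeans(dat)
  rj <- colMeans(dat)
  ssr <- k * sum((si - grand)^2)
  ssc <- n * sum((rj - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (!is.finite(denom) || abs(denom) < 1e-12) {
    warning("degenerate variance; ICC undefined", call. = FALSE)
    return(NA_real_)
  }
  (msr - mse) / denom
}

#' Proportion of adult input attributed to female voices
#'
#' @param counts a named vector (or one-row data frame) containing `FEM`
#'   and `MAL` counts.
#' @return `FEM / (FEM + MAL)`, or `NA` (with a warning) when no adult
#'   speech is present.
#' @export
#' @examples
#' female_adult_proportion(c(CHI = 10, OCH = 0, FEM = 900, MAL = 2100))
female_adult_proportion <- function(counts) {
  if (is.data.frame(counts)) counts <- unlist(counts[1, ])
  fem <- as.numeric(counts[["FEM"]])
  mal <- as.numeric(counts[["MAL"]])
  if (fem + mal <= 0) {
    warning("FEM + MAL is zero; proportion undefined", call. = FALSE)
    return(NA_real_)
  }
  fem / (fem + mal)
}
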