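#' Classifier confusion profile
#'
#' A confusion profile describes, at the population level, how a voice-type
#' classifier transforms true vocalization counts into reported counts.
#' `mu[i, j]` is the expected number of detections attributed to speaker j
#' per true vocalization of speaker i (the diagonal is recall-like, the
#' off-diagonal entries are misattribution rates). Confusion rates vary from
#' recording to recording: the rates `lambda[i, j]` of a given recording are
#' drawn from Gamma distributions with means `mu[i, j]` and shapes
#' `alpha[i, j]` (larger shapes mean more consistent behavior across
#' recordings). `tau` is the dispersion of the double-Poisson count noise
#' (see [ddpo()]).
#'
#' @param mu 4x4 non-negative matrix of mean confusion rates (sources in
#'   rows, targets in columns, order CHI, OCH, FEM, MAL).
#' @param alpha 4x4 matrix of Gamma shapes, all entries >= 1.
#' @param tau positive dispersion of the count noise.
#' @return An object of class `confusion_profile`.
#' @export
#' @examples
#' p <- confusion_profile(mu = diag(4) * 0.7 + 0.02, alpha = matrix(4, 4, 4), tau = 0.8)
#' p
confusion_profile <- function(mu, alpha, tau) {
  mu <- as.matrix(mu)
  alpha <- as.matrix(alpha)
  if (!all(dim(mu) == c(4L, 4L))) stop("mu must be a 4x4 matrix")
  if (!all(dim(alpha) == c(4L, 4L))) stop("alpha must be a 4x4 matrix")
  if (anyNA(mu) || any(mu < 0)) stop("mu must be non-negative")
  if (anyNA(alpha) || any(alpha < 1)) stop("alpha entries must be >= 1")
  if (length(tau) != 1L || is.na(tau) || tau <= 0) stop("tau must be a positive number")
  dimnames(mu) <- dimnames(alpha) <- list(speaker_classes(), speaker_classes())
  structure(list(mu = mu, alpha = alpha, tau = as.numeric(tau)),
            class = "confusion_profile")
}

#' @export
print.confusion_profile <- function(x, ...) {
  cat("<confusion_profile>\n")
  cat("mean confusion rates mu (source rows -> target columns):\n")
  print(round(x$mu, 3))
  cat("Gamma shapes alpha:\n")
  print(round(x$alpha, 2))
  cat(sprintf("count dispersion tau: %.3f\n", x$tau))
  invisible(x)
}

#' Draw recording-specific confusion rates
#'
#' Draws a 4x4 matrix of recording-level confusion rates
#' `lambda[i, j] ~ Gamma(shape = alpha[i, j], mean = mu[i, j])`,
#' independently across cells. Entries with `mu = 0` are fixed at 0.
#'
#' @param profile a [confusion_profile()].
#' @param n number of draws.
#' @return For `n = 1` a 4x4 matrix; otherwise a 4x4xn array.
#' @export
sample_confusion <- function(profile, n = 1) {
  stopifnot(inherits(profile, "confusion_profile"))
  draw1 <- function() {
    lam <- matrix(0, 4, 4, dimnames = dimnames(profile$mu))
    pos <- profile$mu > 0
    lam[pos] <- rgamma(sum(pos), shape = profile$alpha[pos],
                       rate = profile$alpha[pos] / profile$mu[pos])
    lam
  }
  if (n == 1L) return(draw1())
  out <- array(0, dim = c(4, 4, n), dimnames = c(dimnames(profile$mu), list(NULL)))
  for (k in seq_len(n)) out[, , k] <- draw1()
  out
}

#' Simulate classifier counts from true counts
#'
#' Given true per-speaker counts `v` and recording-level confusion rates
#' `lambda`, simulates the classifier's reported counts: each (source i,
#' target j) cell contributes `n[i, j] ~ DPO(lambda[i, j] * v[i], tau)`
#' detections, and the reported count for target j is `sum_i n[i, j]`.
#'
#' @param v length-4 vector of non-negative integer true counts
#'   (CHI, OCH, FEM, MAL).
#' @param lambda 4x4 matrix of confusion rates (e.g. from
#'   [sample_confusion()]).
#' @param tau positive count-noise dispersion.
#' @return Named length-4 integer vector of simulated classifier counts.
#' @export
#' @examples
#' p <- bundled_profile("recall_biased")
#' lam <- sample_confusion(p)
#' simulate_counts(c(5, 0, 3, 1), lam, p$tau)
simulate_counts <- function(v, lambda, tau) {
  v <- as_int_count4(v, "v")
  lambda <- as.matrix(lambda)
  if (!all(dim(lambda) == c(4L, 4L)) || any(lambda < 0)) {
    stop("lambda must be a non-negative 4x4 matrix")
  }
  out <- simulate_counts_cpp(v, lambda, tau)
  setNames(as.integer(out), speaker_classes())
}

#' Exact window-level log likelihood of classifier counts
#'
#' Computes `log P(n | v, lambda, tau)` for a single human-annotated window:
#' the marginal probability of the observed classifier counts `n` given the
#' true counts `v`, summing over all latent decompositions
#' `{n[i, j] >= 0 : sum_i n[i, j] = n[j]}` of the product of per-source
#' double-Poisson terms. Because the decomposition sum factorizes over
#' target classes, it is evaluated exactly as a four-fold convolution of the
#' source pmfs, with no combinatorial enumeration.
#'
#' Counts above `cap` signal windows too long for the marginalization to be
#' meaningful; use shorter (15-s) windows instead.
#'
#' @inheritParams simulate_counts
#' @param n length-4 vector of observed classifier counts.
#' @param cap maximum per-window count admitted (default 40).
#' @return A single log probability.
#' @export
clip_log_likelihood <- function(n, v, lambda, tau, cap = 40L) {
  n <- as_int_count4(n, "n")
  v <- as_int_count4(v, "v")
  if (any(n > cap) || any(v > cap)) {
    stop("per-window counts exceed the cap (", cap,
         "); use smaller windows (15 s) for calibration data")
  }
  lambda <- as.matrix(lambda)
  if (!all(dim(lambda) == c(4L, 4L)) || any(lambda < 0)) {
    stop("lambda must be a non-negative 4x4 matrix")
  }
  clip_loglik_cpp(n, v, lambda, tau)
}

#' Continuous recording-level log likelihood of classifier counts
#'
#' The recording-level counterpart of [clip_log_likelihood()]: true counts
#' `v` are treated as continuous (they are latent parameters at the
#' recording level), and the observed count for each target class j is
#' modeled directly as `n[j] ~ DPO(sum_i lambda[i, j] * v[i], tau)`.
#'
#' @inheritParams clip_log_likelihood
#' @param v length-4 vector of non-negative real (latent) true counts.
#' @return A single log probability, finite for positive `v`.
#' @export
recording_log_likelihood <- function(n, v, lambda, tau) {
  n <- as_int_count4(n, "n")
  v <- as_count4(v, "v")
  lambda <- as.matrix(lambda)
  if (!all(dim(lambda) == c(4L, 4L)) || any(lambda < 0)) {
    stop("lambda must be a non-negative 4x4 matrix")
  }
  rec_loglik_cpp(n, as.numeric(v), lambda, tau)
}

#' Read and write confusion profiles as plain text
#'
#' Profiles are stored as a three-column table (`param`, `source`, `target`,
#' `value`) in tab-separated text: 16 `mu` rows, 16 `alpha` rows and one
#' `tau` row. Round-trip safe.
#'
#' @param profile a [confusion_profile()].
#' @param path file path.
#' @return `read_confusion_profile` returns a [confusion_profile()];
#'   `write_confusion_profile` returns `path` invisibly.
#' @export
write_confusion_profile <- function(profile, path) {
  stopifnot(inherits(profile, "confusion_profile"))
  sp <- speaker_classes()
  rows <- rbind(
    data.frame(param = "mu", source = rep(sp, each = 4), target = rep(sp, 4),
               value = as.vector(t(profile$mu))),
    data.frame(param = "alpha", source = rep(sp, each = 4), target = rep(sp, 4),
               value = as.vector(t(profile$alpha))),
    data.frame(param = "tau", source = "", target = "", value = profile$tau)
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion_profile
#' @export
read_confusion_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "character", "numeric"))
  sp <- speaker_classes()
  take <- function(param) {
    m <- matrix(NA_real_, 4, 4, dimnames = list(sp, sp))
    sub <- tab[tab$param == param, ]
    if (nrow(sub) != 16L) stop("expected 16 ", param, " rows in ", path)
    for (r in seq_len(16L)) m[sub$source[r], sub$target[r]] <- sub$value[r]
    m
  }
  tau <- tab$value[tab$param == "tau"]
  if (length(tau) != 1L) stop("expected one tau row in ", path)
  confusion_profile(take("mu"), take("alpha"), tau)
}

#' Bundled synthetic classifier profiles
#'
#' Two qualitative classifier behavior profiles for tests and simulations,
#' both synthetic (their numeric values are illustrative, not fitted to any
#' corpus). `"precision_biased"` mimics a conservative classifier: low
#' false-positive (off-diagonal) rates but also lower recall, with more
#' variable behavior across recordings (smaller Gamma shapes, more dispersed
#' count noise). `"recall_biased"` mimics a classifier tuned for F-score:
#' higher recall and higher false-positive rates, with more consistent
#' behavior (peaked rate distributions). In both, children are confused
#' mostly with each other and with female adults, and the two adult classes
#' with one another.
#'
#' @param name `"precision_biased"` or `"recall_biased"`.
#' @return A [confusion_profile()].
#' @export
bundled_profile <- function(name = c("precision_biased", "recall_biased")) {
  name <- match.arg(name)
  sp <- speaker_classes()
  if (name == "precision_biased") {
    mu <- matrix(c(
      #        CHI   OCH   FEM   MAL     (targets)
      0.55, 0.04, 0.05, 0.01,   # CHI
      0.10, 0.40, 0.06, 0.02,   # OCH
      0.08, 0.03, 0.60, 0.04,   # FEM
      0.02, 0.02, 0.08, 0.45    # MAL
    ), 4, 4, byrow = TRUE, dimnames = list(sp, sp))
    alpha <- matrix(2, 4, 4, dimnames = list(sp, sp))
    diag(alpha) <- 3
    tau <- 0.6
  } else {
    mu <- matrix(c(
      0.80, 0.08, 0.10, 0.02,
      0.18, 0.65, 0.12, 0.04,
      0.14, 0.06, 0.85, 0.07,
      0.04, 0.04, 0.14, 0.70
    ), 4, 4, byrow = TRUE, dimnames = list(sp, sp))
    alpha <- matrix(5, 4, 4, dimnames = list(sp, sp))
    diag(alpha) <- 10
    tau <- 0.9
  }
  confusion_profile(mu, alpha, tau)
}
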