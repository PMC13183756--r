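#' Configuration of a sensitivity simulation
#'
#' Defines one simulation experiment for assessing how classification
#' errors distort an analysis pipeline: a rule for drawing (or fixing) the
#' true parameter of interest, a generator producing true counts given that
#' parameter, the classifier's confusion profile, and the analysis pipeline
#' run on the distorted counts.
#'
#' @param theta_spec either a single number (the parameter is fixed, e.g. 0
#'   for a null hypothesis) or a function `function() value` drawing it.
#' @param n_replicates number of simulated datasets.
#' @param generator function `function(theta_hat)` returning a tibble of
#'   true counts with columns `CHI`, `OCH`, `FEM`, `MAL` (one row per
#'   unit).
#' @param profile a [confusion_profile()].
#' @param pipeline either a function `function(counts) statistic` or the
#'   name of a registered pipeline (see [sensitivity_pipelines()]).
#' @param seed integer seed.
#' @return A list of class `sensitivity_config`.
#' @export
sensitivity_config <- function(theta_spec, n_replicates, generator, profile,
                               pipeline, seed = 1) {
  stopifnot(n_replicates >= 1)
  if (is.character(pipeline)) {
    reg <- sensitivity_pipelines()
    if (!pipeline %in% names(reg)) {
      stop("unknown pipeline '", pipeline, "'; registered: ",
           paste(names(reg), collapse = ", "))
    }
    pipeline <- reg[[pipeline]]
  }
  structure(list(theta_spec = theta_spec, n_replicates = as.integer(n_replicates),
                 generator = generator, profile = profile,
                 pipeline = pipeline, seed = as.integer(seed)),
            class = "sensitivity_config")
}

#' Registered analysis pipelines
#'
#' Named statistics available to [run_sensitivity()] by name:
#' `"female_proportion"` (mean female share of adult counts across units)
#' and `"chi_fem_correlation"` (Pearson correlation between CHI and FEM
#' counts across units).
#'
#' @return Named list of functions taking a count tibble.
#' @export
sensitivity_pipelines <- function() {
  list(
    female_proportion = function(counts) {
      mean(counts$FEM / pmax(counts$FEM + counts$MAL, 1))
    },
    chi_fem_correlation = function(counts) {
      if (sd(counts$CHI) < 1e-12 || sd(counts$FEM) < 1e-12) return(0)
      cor(counts$CHI, counts$FEM)
    }
  )
}

#' Run a sensitivity simulation
#'
#' For each replicate: draw the true parameter, simulate true counts from
#' the generator, simulate the classifier's counts through the confusion
#' model (recording-specific rates are redrawn for every unit), run the
#' pipeline on the distorted counts, and record the measured statistic.
#' If the measured values depart systematically from the true parameter,
#' the pipeline is sensitive to classification errors.
#'
#' @param config a [sensitivity_config()].
#' @return A tibble of class `sensitivity_result` with columns `replicate`,
#'   `theta_hat` and `theta_meas`.
#' @export
run_sensitivity <- function(config) {
  stopifnot(inherits(config, "sensitivity_config"))
  set.seed(config$seed)
  draw_theta <- if (is.function(config$theta_spec)) config$theta_spec
                else function() config$theta_spec
  rows <- vector("list", config$n_replicates)
  for (rep in seq_len(config$n_replicates)) {
    theta_hat <- draw_theta()
    truth <- config$generator(theta_hat)
    meas <- apply_classifier(truth, config$profile)
    rows[[rep]] <- tibble::tibble(replicate = rep, theta_hat = theta_hat,
                                  theta_meas = config$pipeline(meas))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' The female-adult-proportion sensitivity experiment
#'
#' The reference generative experiment for measurement distortion of the
#' female share of adult input. For each sample the true counts are
#' `CHI = 1500`; `OCH = 0` or `1000` each with probability 1/2;
#' `FEM = 3000 p` and `MAL = 3000 (1 - p)` with `p ~ uniform(0, 1)` (total
#' adult input fixed at 3000). The classifier's counts are simulated with
#' recording-specific confusion rates redrawn per sample, and the measured
#' proportion `n_FEM / (n_FEM + n_MAL)` is compared to the true `p`.
#'
#' @param profile a [confusion_profile()].
#' @param n_samples number of samples (default 2000).
#' @param seed integer seed.
#' @return A `sensitivity_result` tibble with `theta_hat = p` and
#'   `theta_meas` the measured proportion.
#' @export
female_proportion_experiment <- function(profile, n_samples = 2000, seed = 1) {
  gen <- function(p) {
    fem <- as.integer(round(3000 * p))
    tibble::tibble(CHI = 1500L,
                   OCH = sample(c(0L, 1000L), 1),
                   FEM = fem, MAL = 3000L - fem)
  }
  cfg <- sensitivity_config(theta_spec = function() runif(1),
                            n_replicates = n_samples, generator = gen,
                            profile = profile,
                            pipeline = function(counts) {
                              female_adult_proportion(unlist(counts[1, ]))
                            },
                            seed = seed)
  run_sensitivity(cfg)
}

#' Summarize a sensitivity result as a bias curve
#'
#' Local summary of `theta_meas` against `theta_hat` on a grid: within a
#' window of half-width `h` around each grid point, the running median,
#' mean, and central 80% band of the measured statistic.
#'
#' @param result a `sensitivity_result`.
#' @param grid grid of true-parameter values.
#' @param h window half-width.
#' @return A tibble with columns `theta_hat`, `n`, `mean`, `median`,
#'   `lo10`, `hi90`.
#' @export
bias_curve <- function(result, grid = seq(0.05, 0.95, by = 0.05), h = 0.05) {
  rows <- lapply(grid, function(g) {
    sel <- abs(result$theta_hat - g) <= h
    x <- result$theta_meas[sel]
    tibble::tibble(theta_hat = g, n = sum(sel),
                   mean = if (length(x)) mean(x) else NA_real_,
                   median = if (length(x)) median(x) else NA_real_,
                   lo10 = if (length(x)) unname(quantile(x, 0.1)) else NA_real_,
                   hi90 = if (length(x)) unname(quantile(x, 0.9)) else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Monte-Carlo null-hypothesis test
#'
#' Compares an observed statistic to its distribution under a null
#' simulation, with the add-one convention that guarantees a positive
#' p-value: `p = (1 + #{null >= observed}) / (N + 1)`.
#'
#' @param observed_stat the observed value of the statistic.
#' @param null_stats either a numeric vector of null replicates or a
#'   `sensitivity_result` run under the null (its `theta_meas` column is
#'   used).
#' @return The Monte-Carlo exceedance probability.
#' @export
null_test <- function(observed_stat, null_stats) {
  if (inherits(null_stats, "sensitivity_result")) {
    null_stats <- null_stats$theta_meas
  }
  null_stats <- null_stats[is.finite(null_stats)]
  if (!length(null_stats)) stop("no null replicates")
  (1 + sum(null_stats >= observed_stat)) / (length(null_stats) + 1)
}
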