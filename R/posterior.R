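#' @title Posterior sample containers
#' @description MCMC output is stored as an iterations x chains x parameters
#'   array with split-R-hat and effective-sample-size diagnostics computed
#'   for every parameter.
#' @name posterior_samples
NULL

new_posterior_samples <- function(chain_draws, param_names, model = "model",
                                  config = list()) {
  n_iter <- nrow(chain_draws[[1]])
  n_chain <- length(chain_draws)
  arr <- array(NA_real_, dim = c(n_iter, n_chain, length(param_names)),
               dimnames = list(NULL, NULL, param_names))
  for (ch in seq_len(n_chain)) arr[, ch, ] <- chain_draws[[ch]]
  structure(list(draws = arr, model = model, config = config,
                 flagged = character()),
            class = "posterior_samples")
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction computed on split chains (each chain halved),
#' so that it detects both between-chain disagreement and within-chain
#' trends.
#'
#' @param x an iterations x chains matrix of draws for one parameter.
#' @return The split-R-hat value (1 at perfect convergence).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(x)), function(ch) {
    cbind(x[seq_len(half), ch], x[(n - half + 1):n, ch])
  }))
  m <- ncol(splits)
  nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W < 1e-12) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size pooled across chains, with
#' Geyer's initial-positive-sequence truncation of the autocorrelation sum.
#'
#' @inheritParams split_rhat
#' @return Estimated number of effectively independent draws.
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  W <- mean(apply(x, 2, var))
  if (W < 1e-12) return(n * m)
  # chain-averaged autocorrelations
  max_lag <- min(n - 1, 500)
  rho <- rep(0, max_lag)
  for (ch in seq_len(m)) {
    a <- acf(x[, ch], lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
    rho <- rho + a / m
  }
  # sum paired autocorrelations while they remain positive
  s <- 0
  t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- n * m / (1 + 2 * s)
  max(min(ess, n * m), 1)
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<posterior_samples: %s> %d iterations x %d chains x %d parameters\n",
              x$model, d[1], d[2], d[3]))
  if (length(x$flagged)) {
    cat("convergence flagged for:", paste(head(x$flagged, 8), collapse = ", "),
        if (length(x$flagged) > 8) "..." else "", "\n")
  }
  print(summary(x, params = head(dimnames(x$draws)[[3]], 10)))
  invisible(x)
}

#' Summarize posterior samples
#'
#' @param object a `posterior_samples` object.
#' @param params optional character vector of parameter names (default all).
#' @param probs quantile levels for the credible bounds.
#' @param ... unused.
#' @return A tibble with one row per parameter: mean, sd, quantiles, split
#'   R-hat and effective sample size.
#' @export
summary.posterior_samples <- function(object, params = NULL,
                                      probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                                      ...) {
  all_params <- dimnames(object$draws)[[3]]
  if (is.null(params)) params <- all_params
  rows <- lapply(params, function(p) {
    x <- object$draws[, , p, drop = TRUE]
    x <- as.matrix(x)
    q <- quantile(x, probs)
    tibble::tibble(param = p, mean = mean(x), sd = sd(x),
                   !!!setNames(as.list(q), paste0("q", probs * 100)),
                   rhat = split_rhat(x), ess = ess_basic(x))
  })
  dplyr::bind_rows(rows)
}

#' Extract pooled draws for one parameter
#'
#' @param fit a `posterior_samples` object.
#' @param param parameter name.
#' @return Numeric vector pooling all chains.
#' @export
posterior_draws <- function(fit, param) {
  stopifnot(inherits(fit, "posterior_samples"))
  if (!param %in% dimnames(fit$draws)[[3]]) stop("unknown parameter: ", param)
  as.vector(fit$draws[, , param])
}

#' Central credible interval for one parameter
#'
#' @inheritParams posterior_draws
#' @param level interval mass (e.g. 0.95). `level = 1` returns the full
#'   posterior range.
#' @return Length-2 vector (lower, upper).
#' @export
posterior_interval <- function(fit, param, level = 0.95) {
  x <- posterior_draws(fit, param)
  if (level >= 1) return(range(x))
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a)))
}

check_convergence <- function(fit, watch, threshold = 1.05) {
  s <- summary(fit, params = watch)
  bad <- s$param[!is.na(s$rhat) & s$rhat > threshold]
  if (length(bad)) {
    fit$flagged <- bad
    warning("MCMC convergence flagged (split R-hat > ", threshold, ") for: ",
            paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  fit
}

#' MCMC configuration
#'
#' @param chains number of chains.
#' @param warmup adaptation iterations discarded per chain.
#' @param iter retained sampling iterations per chain.
#' @param seed integer seed; chain ch is seeded deterministically from
#'   `seed` and `ch`, making every run exactly reproducible.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, iter = 1000, seed = 1) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed)),
            class = "mcmc_config")
}

chain_seed <- function(cfg, chain) (cfg$seed %% 1000000L) * 1000L + chain
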