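#' The renormalized double-Poisson distribution
#'
#' Density and random generation for Efron's double-Poisson count
#' distribution parameterized by its mean `m` and dispersion `tau`, with the
#' `0^0 := 1` convention at zero and the density renormalized by truncated
#' summation so that probabilities sum to one. The distribution has mean
#' approximately `m` and variance approximately `m / tau`: `tau = 1` recovers
#' the Poisson exactly, `tau < 1` gives overdispersion and `tau > 1`
#' underdispersion. It is used as the count-noise law of the classifier
#' model: each true vocalization of speaker i contributes detections
#' attributed to speaker j with mean `lambda[i, j]`.
#'
#' @param x vector of non-negative integer quantiles.
#' @param n number of draws.
#' @param m mean, a single non-negative number. `m = 0` yields a point mass
#'   at zero.
#' @param tau dispersion, a single positive number.
#' @param log logical; if `TRUE`, log probabilities are returned.
#' @return `ddpo` a numeric vector of (log) probabilities; `rdpo` an integer
#'   vector of draws.
#' @export
#' @examples
#' ddpo(0, m = 2, tau = 1)     # exp(-2): Poisson at tau = 1
#' sum(ddpo(0:200, m = 3, tau = 0.5))
ddpo <- function(x, m, tau, log = FALSE) {
  stopifnot(length(m) == 1L, length(tau) == 1L)
  if (is.na(m) || m < 0) stop("m must be a non-negative number")
  if (is.na(tau) || tau <= 0) stop("tau must be a positive number")
  if (any(abs(x - round(x)) > 1e-8)) stop("x must be integer-valued")
  ddpo_cpp(as.integer(round(x)), m, tau, isTRUE(log))
}

#' @rdname ddpo
#' @export
rdpo <- function(n, m, tau) {
  stopifnot(length(m) == 1L, length(tau) == 1L)
  if (is.na(m) || m < 0) stop("m must be a non-negative number")
  if (is.na(tau) || tau <= 0) stop("tau must be a positive number")
  rdpo_cpp(as.integer(n), m, tau)
}

#' @rdname ddpo
#' @param ... passed to `ddpo`.
#' @details `dpo_pmf` is a convenience alias for `ddpo` on the probability
#'   scale.
#' @export
dpo_pmf <- function(x, m, tau, ...) ddpo(x, m, tau, log = FALSE, ...)
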