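# Shared fixtures and independent oracles for the test suite.

# A fixed, asymmetric confusion-rate matrix used across likelihood tests.
test_lambda <- function() {
  matrix(c(0.70, 0.05, 0.10, 0.02,
           0.10, 0.50, 0.05, 0.03,
           0.08, 0.04, 0.80, 0.05,
           0.02, 0.03, 0.10, 0.60),
         4, 4, byrow = TRUE,
         dimnames = list(speaker_classes(), speaker_classes()))
}

# Near-perfect classifier: identity rates with vanishing variability and
# near-degenerate count noise.
identity_profile <- function(tau = 1000) {
  confusion_profile(mu = diag(4), alpha = matrix(1e6, 4, 4), tau = tau)
}

# Brute-force enumeration oracle for the window likelihood: sums the product
# of per-source DPO terms over all decompositions {n_ij : sum_i n_ij = n_j},
# independently per target class.  Deliberately separate from the package's
# convolution-based implementation.
enum_clip_loglik <- function(n, v, lam, tau) {
  total <- 0
  for (j in 1:4) {
    nj <- n[j]
    pj <- 0
    for (a in 0:nj) for (b in 0:(nj - a)) for (cc in 0:(nj - a - b)) {
      d <- nj - a - b - cc
      dec <- c(a, b, cc, d)
      pj <- pj + prod(vapply(1:4, function(i) ddpo(dec[i], lam[i, j] * v[i], tau),
                             numeric(1)))
    }
    total <- total + log(pj)
  }
  total
}

# Exact moments of the renormalized double-Poisson by direct summation.
dpo_exact_moments <- function(m, tau, ymax = NULL) {
  if (is.null(ymax)) ymax <- ceiling(m + 25 * sqrt(m / tau + 1)) + 50
  y <- 0:ymax
  p <- ddpo(y, m, tau)
  mu <- sum(y * p)
  list(mean = mu, var = sum(y^2 * p) - mu^2)
}

# Minimal segment tibble builder.
make_segments <- function(recording_id, speaker, onset, offset,
                          annotator_id = "human") {
  tibble::tibble(recording_id = recording_id, annotator_id = annotator_id,
                 speaker = speaker, onset = onset, offset = offset)
}
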