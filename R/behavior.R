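#' Parameters of the speech behavior model
#'
#' The behavior model is a hierarchical log-link GLM for the expected number
#' of vocalizations of each speaker class per recording. Expected log rates
#' decompose into a population level (`mu_pop`), corpus- and child-level
#' Gaussian deviations (SDs `sigma_corpus`, `sigma_child`), sibling effects
#' on other-child and adult speech (`beta_sib_och`, `beta_sib_adu`; siblings
#' never act on the key child's rate directly), and a child-specific
#' developmental slope on the key child's output. Slopes are distributed
#' `N(alpha_dev, sigma_dev)` and act through an age basis that grows
#' linearly on the log scale up to `plateau_months` (24) and is flat
#' afterwards, so that children's speech quantities at birth are equivalent
#' up to their child-level rate. A long-term effect of adult input on child
#' output (`beta_dev`) interacts with the same age basis through the
#' standardized child-level expected adult rate. Realized counts are
#' gamma-Poisson (negative binomial) around the GLM mean with dispersion
#' `phi`.
#'
#' Default values define the package's reference simulation conditions; see
#' the methods vignette for their rationale.
#'
#' @param mu_pop length-4 vector of population log rates (CHI, OCH, FEM,
#'   MAL) per recording.
#' @param sigma_corpus,sigma_child non-negative SDs of corpus- and
#'   child-level deviations of the log rates.
#' @param beta_sib_och effect of siblings on the other-child log rate.
#' @param beta_sib_adu effect of siblings on the female- and male-adult log
#'   rates.
#' @param alpha_dev mean of the child developmental slopes.
#' @param sigma_dev SD of the child slopes.
#' @param beta_dev long-term effect of standardized child-level adult input
#'   on child output, interacting with age.
#' @param phi positive gamma-Poisson dispersion of counts around the mean.
#' @param sibling_coding `"indicator"` (any siblings vs none, the default)
#'   or `"count"` (number of siblings).
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(mu_pop = log(c(CHI = 400, OCH = 150, FEM = 600, MAL = 200)),
                            sigma_corpus = 0.2, sigma_child = 0.3,
                            beta_sib_och = 1.1, beta_sib_adu = -0.22,
                            alpha_dev = 1.0, sigma_dev = 0.3,
                            beta_dev = 0.25, phi = 5,
                            sibling_coding = c("indicator", "count")) {
  sibling_coding <- match.arg(sibling_coding)
  mu_pop <- as_count4(exp(mu_pop), "exp(mu_pop)")  # validates length/order
  mu_pop <- log(mu_pop)
  stopifnot(sigma_corpus >= 0, sigma_child >= 0, sigma_dev >= 0, phi > 0)
  structure(list(mu_pop = setNames(mu_pop, speaker_classes()),
                 sigma_corpus = sigma_corpus, sigma_child = sigma_child,
                 beta_sib_och = beta_sib_och, beta_sib_adu = beta_sib_adu,
                 alpha_dev = alpha_dev, sigma_dev = sigma_dev,
                 beta_dev = beta_dev, plateau_months = 24, phi = phi,
                 sibling_coding = sibling_coding),
            class = "behavior_params")
}

#' @export
print.behavior_params <- function(x, ...) {
  cat("<behavior_params>\n")
  cat("  mu_pop (log rates):", paste(sprintf("%s=%.2f", speaker_classes(), x$mu_pop),
                                     collapse = ", "), "\n")
  cat(sprintf("  sigma_corpus=%.2f sigma_child=%.2f\n", x$sigma_corpus, x$sigma_child))
  cat(sprintf("  beta_sib_och=%.2f beta_sib_adu=%.2f (%s coding)\n",
              x$beta_sib_och, x$beta_sib_adu, x$sibling_coding))
  cat(sprintf("  alpha_dev=%.2f sigma_dev=%.2f beta_dev=%.2f\n",
              x$alpha_dev, x$sigma_dev, x$beta_dev))
  cat(sprintf("  plateau=%d months, phi=%.1f\n", x$plateau_months, x$phi))
  invisible(x)
}

#' Developmental age basis
#'
#' Age enters all developmental effects through
#' `min(age, 24) / 24`: log-linear growth up to a 24-month threshold, flat
#' thereafter.
#'
#' @param age_months non-negative age(s) in months.
#' @return Value(s) in `[0, 1]`.
#' @export
#' @examples
#' age_basis(c(0, 12, 24, 36))
age_basis <- function(age_months) {
  if (any(is.na(age_months)) || any(age_months < 0)) {
    stop("age_months must be non-negative")
  }
  pmin(age_months, 24) / 24
}

#' Child state for rate evaluation
#'
#' Bundles the child-level quantities entering [expected_rates()]: the
#' child-level log rates, the sibling covariate, the child's developmental
#' slope and its standardized adult-input level.
#'
#' @param mu_child length-4 vector of child-level log rates.
#' @param n_siblings non-negative integer.
#' @param alpha_c_dev the child's developmental slope.
#' @param adult_input_level standardized child-level expected adult input.
#' @param child_id,corpus_id optional identifiers.
#' @return A list of class `child_state`.
#' @export
child_state <- function(mu_child, n_siblings = 0, alpha_c_dev = 0,
                        adult_input_level = 0, child_id = "child",
                        corpus_id = "corpus") {
  mu_child <- setNames(as.numeric(as_count4(exp(mu_child), "exp(mu_child)")),
                       speaker_classes())
  structure(list(child_id = child_id, corpus_id = corpus_id,
                 mu_child = log(mu_child), n_siblings = as.integer(n_siblings),
                 alpha_c_dev = alpha_c_dev,
                 adult_input_level = adult_input_level),
            class = "child_state")
}

sibling_covariate <- function(n_siblings, coding) {
  if (coding == "indicator") as.numeric(n_siblings > 0) else as.numeric(n_siblings)
}

#' Expected vocalization rates for one child at a given age
#'
#' Evaluates the behavior GLM: for speaker class s,
#' `log rate_s = mu_child_s + [s == OCH] beta_sib_och * sib
#'             + [s in {FEM, MAL}] beta_sib_adu * sib
#'             + [s == CHI] (alpha_c_dev + beta_dev * adult_input) * age_basis(age)`.
#'
#' @param params a [behavior_params()].
#' @param child a [child_state()].
#' @param age_months the child's age at the recording.
#' @return Named length-4 vector of positive expected counts per recording.
#' @export
expected_rates <- function(params, child, age_months) {
  stopifnot(inherits(params, "behavior_params"), inherits(child, "child_state"))
  sib <- sibling_covariate(child$n_siblings, params$sibling_coding)
  ab <- age_basis(age_months)
  eta <- child$mu_child
  eta["OCH"] <- eta["OCH"] + params$beta_sib_och * sib
  eta["FEM"] <- eta["FEM"] + params$beta_sib_adu * sib
  eta["MAL"] <- eta["MAL"] + params$beta_sib_adu * sib
  eta["CHI"] <- eta["CHI"] +
    (child$alpha_c_dev + params$beta_dev * child$adult_input_level) * ab
  exp(eta)
}

# child-level standardized adult-input levels, shared by the generator and
# the samplers: log of the child-level expected FEM+MAL rate (including the
# sibling effect), z-scored across children
adult_input_levels <- function(eta_fem, eta_mal) {
  la <- pmax(eta_fem, eta_mal) + log(exp(eta_fem - pmax(eta_fem, eta_mal)) +
                                       exp(eta_mal - pmax(eta_fem, eta_mal)))
  if (length(la) < 2 || sd(la) < 1e-12) return(rep(0, length(la)))
  (la - mean(la)) / sd(la)
}

#' Simulate true vocalization counts for a synthetic cohort
#'
#' Draws corpus- and child-level deviations and child slopes from their
#' Gaussian hierarchies, evaluates the behavior GLM at each recording age,
#' and generates gamma-Poisson (negative binomial) counts around the mean.
#' Each child contributes `recordings_per_child` recordings at ages spaced
#' two months apart from a uniform baseline age.
#'
#' @param params a [behavior_params()].
#' @param children either a positive integer (number of children; corpus
#'   membership and sibling counts are then generated) or a data frame with
#'   columns `child_id`, `corpus_id`, `n_siblings` and optionally
#'   `age_base`.
#' @param recordings_per_child number of recordings per child.
#' @param seed optional integer seed.
#' @param n_corpora number of corpora when `children` is a count.
#' @return A tibble with one row per recording: `recording_id`, `child_id`,
#'   `corpus_id`, `age_months`, `n_siblings` and true counts `CHI`, `OCH`,
#'   `FEM`, `MAL`. The drawn latent effects are attached as attribute
#'   `"latents"`.
#' @export
#' @examples
#' corpus <- simulate_true_counts(behavior_params(), children = 10,
#'                                recordings_per_child = 2, seed = 1)
#' nrow(corpus)  # 20
simulate_true_counts <- function(params, children, recordings_per_child = 5,
                                 seed = NULL, n_corpora = 4) {
  stopifnot(inherits(params, "behavior_params"))
  if (!is.null(seed)) set.seed(seed)
  sp <- speaker_classes()
  if (is.numeric(children) && length(children) == 1L) {
    n <- as.integer(children)
    children <- tibble::tibble(
      child_id = sprintf("child%03d", seq_len(n)),
      corpus_id = sprintf("corpus%d", 1 + (seq_len(n) - 1L) %% n_corpora),
      n_siblings = sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    )
  }
  children <- tibble::as_tibble(children)
  n_child <- nrow(children)
  if (!"age_base" %in% names(children)) {
    children$age_base <- runif(n_child, 2, 24)
  }
  corpora <- unique(children$corpus_id)
  dev_corpus <- matrix(rnorm(length(corpora) * 4, 0, params$sigma_corpus),
                       length(corpora), 4, dimnames = list(corpora, sp))
  dev_child <- matrix(rnorm(n_child * 4, 0, params$sigma_child),
                      n_child, 4, dimnames = list(children$child_id, sp))
  slope <- rnorm(n_child, params$alpha_dev, params$sigma_dev)

  sib <- sibling_covariate(children$n_siblings, params$sibling_coding)
  eta_child <- sweep(dev_child, 2, params$mu_pop, "+") +
    dev_corpus[children$corpus_id, , drop = FALSE]
  A <- adult_input_levels(eta_child[, "FEM"] + params$beta_sib_adu * sib,
                          eta_child[, "MAL"] + params$beta_sib_adu * sib)

  rows <- list()
  rec <- 0L
  for (c in seq_len(n_child)) {
    st <- child_state(mu_child = eta_child[c, ],
                      n_siblings = children$n_siblings[c],
                      alpha_c_dev = slope[c], adult_input_level = A[c],
                      child_id = children$child_id[c],
                      corpus_id = children$corpus_id[c])
    for (k in seq_len(recordings_per_child)) {
      rec <- rec + 1L
      age <- children$age_base[c] + 2 * (k - 1)
      m <- expected_rates(params, st, age)
      v <- rnbinom(4, size = params$phi, mu = m)
      rows[[rec]] <- tibble::tibble(
        recording_id = sprintf("rec%05d", rec),
        child_id = children$child_id[c], corpus_id = children$corpus_id[c],
        age_months = age, n_siblings = children$n_siblings[c],
        CHI = v[1], OCH = v[2], FEM = v[3], MAL = v[4]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "latents") <- list(dev_corpus = dev_corpus, dev_child = dev_child,
                               slope = slope, adult_input_level = A)
  out
}
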