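---
title: "Modeling and correcting speaker-classification errors in vocalization counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and correcting speaker-classification errors in vocalization counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalib)
```

## The measurement problem

Long-form child-centered audio recordings are annotated by automatic
voice-type classifiers that attribute each detected speech segment (a
"vocalization") to one of four speaker classes: the key child wearing the
device (CHI), other children (OCH), female adults (FEM), and male adults
(MAL). The per-speaker vocalization counts of each recording are the raw
material of many analyses of language acquisition: how much speech a child
hears, from whom, and how much the child produces.

Classifiers confuse speakers. A detector that attributes some female-adult
speech to the key child does not merely add noise to both counts: it
couples them. In causal terms, classification errors open *biasing paths*
between measured quantities, which can inflate correlations between
speakers, distort measured proportions (e.g. the female share of adult
input), and bias estimated effects of covariates (e.g. the effect of
siblings on adult input) — up to changing their sign. vocalib implements a
joint Bayesian model of speech behavior and classifier behavior that (a)
simulates these distortions for sensitivity analysis and null-hypothesis
testing, and (b) recovers calibrated estimates by treating the true counts
as latent variables.

## The confusion model

Let `v_i` be the true number of vocalizations of speaker class `i` in some
unit of audio. Each true vocalization of `i` causes the classifier to
produce a random number of detections attributed to each class `j`; the
total attributed to `j` from source `i` is `n_ij`, and only the row sums
`n_j = sum_i n_ij` are observed. Counts are modeled with Efron's
double-Poisson distribution,

```
n_ij ~ DPO(lambda_ij * v_i, tau),
```

with mean `lambda_ij * v_i` and variance `lambda_ij * v_i / tau`. Unlike a
binomial thinning model, this allows one true vocalization to yield several
detections (classifiers split segments), and `tau` captures over- or
under-dispersion of that process (`tau = 1` is exactly Poisson). We commit
to the renormalized form of Efron's density: the unnormalized terms (with
`0^0 := 1` at zero) are divided by their truncated sum, carried until the
tail is numerically negligible (relative tail mass below about 1e-20); for
large `mean * tau` the package switches to Efron's analytic normalizer,
which is accurate to well below the Monte-Carlo noise of any quantity we
compute. One consequence worth knowing: the renormalized distribution's
exact moments deviate slightly from the nominal `(m, m/tau)` — about 0.9%
on the mean at `m = 5, tau = 0.5`, growing to tens of percent at means
well below one when `tau != 1` — an intrinsic property of the
double-Poisson family, not an implementation artifact. The generator and
every likelihood share the same renormalized form, so inference remains
internally coherent; tests distinguish "sampler matches distribution"
(exact moments) from "distribution matches nominal moments" (approximation
quality, asserted where means are moderate).

The confusion rates `lambda_ij` vary across recordings (microphone
placement, noise, voices), modeled as

```
lambda_kij ~ Gamma(shape = alpha_ij, mean = mu_ij),
```

independently across cells and recordings. `mu` is the classifier's mean
confusion matrix; `alpha` measures its consistency. Priors:
`mu_ij ~ Exponential(1)` (weakly informative on rates of order one),
`alpha_ij ~ Pareto(1, 1.5)` truncated to `>= 1`, and a single shared
`tau ~ half-normal(1)`. The Pareto prior is part of the model definition;
the exponential prior on `mu` and the half-normal on `tau` are package
choices (no canonical values exist), and a single `tau` is shared across
all cells, as the recording-level observation model suggests.

### Likelihoods: exact at the window level, continuous at the recording level

Calibration data are short human-annotated windows in which both the true
counts `v` and the classifier counts `n` are known. The likelihood of `n`
given `v` marginalizes the unobserved decomposition `n_ij`:

```
P(n_j | v) = sum over {n_ij >= 0, sum_i n_ij = n_j} of prod_i P(n_ij | v_i)
```

Because the `n_ij` are independent given `v`, this sum is exactly the
convolution of the four source distributions evaluated at `n_j`, and it
factorizes over target classes. The package computes it by iterated
convolution of the per-source pmfs — exact, with none of the combinatorial
cost of enumerating decompositions (the enumeration is retained in the test
suite as an independent oracle). Counts above a cap of 40 per window abort
with an error advising shorter windows: calibration clips are split into
15-second windows, which keeps counts small and the marginal informative.
Windows are assigned by vocalization onset (a vocalization belongs to the
window containing its onset), a rule chosen because it never double-counts
and is independent of segment order; no convention is stated for boundary
straddlers in the data formats we mirror, so this choice is flagged as one
to vary in sensitivity checks.

For the bulk of the audio only classifier counts exist, and recording-level
true counts are latent. There the package uses the continuous
approximation

```
n_kj ~ DPO(sum_i lambda_kij * v_ki, tau)
```

with `v_ki > 0` real-valued — counts at the recording level are in the
hundreds, where the discreteness of `v` is immaterial.

## The behavior model

Expected vocalization rates per recording follow a hierarchical log-link
GLM. For speaker class `s`, child `c`, recording at age `a` (months):

```
log rate_s = mu_pop_s + dev_corpus_s + dev_child_s
           + [s = OCH]  beta_sib_och * sib
           + [s in {FEM, MAL}] beta_sib_adu * sib
           + [s = CHI]  (alpha_dev_c + beta_dev * A_c) * min(a, 24) / 24
```

- Corpus- and child-level deviations are Gaussian with SDs `sigma_corpus`
  and `sigma_child` (shared across speaker classes).
- `sib` is by default a binary indicator (any siblings vs none), matching
  the headline contrasts this model is used for; a count-coded variant is
  available. Siblings act on other-child and adult rates, never directly
  on the key child.
- Each child has a developmental slope `alpha_dev_c ~ N(alpha_dev,
  sigma_dev)` acting through an age basis that is linear up to 24 months
  and flat beyond. At age zero the basis vanishes, so children's output
  rates at birth are equivalent up to their child-level rate — individual
  developmental variation emerges with age. The 24-month plateau is a
  fixed constant of the model; estimating its location is out of scope.
- `A_c` is the long-term adult-input level of child `c`: the log of the
  child-level expected FEM + MAL rate (including the sibling effect),
  z-scored across children. Standardization puts `beta_dev` on the same
  N(0, 1) prior scale as the other effects.

Realized counts are gamma-Poisson (negative binomial) around the GLM mean
with dispersion `phi`. This count law is isolated in one function of the
generator and one density in the samplers, so an implementer preferring a
different overdispersion family can swap it. In the joint model the latent
`v` is continuous with a Gamma prior moment-matched to that count law:
shape `phi * m / (phi + m)`, so that the latent variance is the full
`m + m^2 / phi` rather than the Gamma mixing layer's `m^2 / phi` alone —
at moderate means with larger `phi` the Poisson layer's share is not
negligible, and dropping it demonstrably narrows the latent intervals
below their nominal coverage.

Priors: `N(0, 1)` for unconstrained effects, half-normal(1) for hierarchy
SDs, `N(5, 3)` for the population log rates (weakly informative on counts
per recording), and `1 + Exponential(0.1)` for `phi` — dispersion below 1
would mean a between-recording coefficient of variation above 100% for the
same child, outside the plausible range for day-long recordings, and it
would also place non-negligible mass on true counts of exactly zero, which
the continuous latent cannot represent. All prior scales are configurable
through the fit's `behavior_config`.

### Reference simulation conditions

The generator's defaults define the package's reference conditions:
population rates of 400 (CHI at birth), 150 (OCH), 600 (FEM) and 200 (MAL)
vocalizations per recording day-window; `sigma_corpus = 0.2`,
`sigma_child = 0.3`; a sibling effect of `+1.1` on OCH (children without
siblings receive roughly two-thirds less other-child speech) and `-0.22`
on adults (a ~20% reduction); `alpha_dev = 1.0` (output roughly triples
from birth to the plateau), `sigma_dev = 0.3`, `beta_dev = 0.25`,
`phi = 5`. Cohorts assign children round-robin to four corpora, draw 0/1/2
siblings with probabilities 0.4/0.4/0.2, and give each child a baseline age
uniform on 2–24 months with recordings two months apart — a longitudinal
design in which the age effect is identified both across and (weakly)
within children. These magnitudes were chosen once to be realistic for
day-long recordings in this field; they are not fitted to any dataset.

What the generator deliberately does not emulate: overlapping speech,
segment-level timing structure (turn taking), minimum-duration or
quantization constraints of specific classifiers, covariate-dependent
confusion rates, and annotator disagreement about ground truth. Passing
tests therefore demonstrate correctness of the inference under the model's
own assumptions, not robustness to these real-data features.

## Joint calibration

The joint posterior couples everything: behavior parameters, latent true
counts per recording, per-recording confusion rates, and the confusion
profile, with the exact window likelihood on calibration clips and the
continuous likelihood on recording-level classifier counts. The naive
comparator (`naive_fit()`) fits the same behavior model with classifier
counts plugged in as truth; both consume identical inputs.

### Sampling

The posterior is explored with an adaptive Metropolis-within-Gibbs
sampler written in compiled code: every scalar gets a random-walk proposal
(Gaussian on unconstrained scales, log-normal for positive quantities)
whose step size adapts toward a 0.44 acceptance rate during warmup and is
then frozen. Gradient-based samplers are the field's default for such
models; a component-wise scheme was chosen here because the marginalized
likelihoods make single-scalar updates cheap and local, and because it
keeps the package free of an external probabilistic-programming runtime.
Its known cost — slow mixing along posterior ridges — is addressed with
dedicated joint moves along the directions that dominate this model:

- `v_ri` against its confusion-rate row (`v -> c v`, `lambda_i. ->
  lambda_i. / c`), which leaves all observation means invariant;
- a global per-source rescaling (all `v_.i` up, the whole `lambda` row
  `i` and `mu_i.` down), the direction in which only the calibration
  clips pin the absolute scale;
- the key-child intercept against the slope hierarchy (scaled by the mean
  age basis);
- each child's CHI deviation against its slope;
- the OCH and adult intercepts against their sibling effects.

Some scalar blocks (per-recording confusion rates, child deviations) are
updated in a random scan, each with probability 1/2 per sweep.

Defaults are 4 chains of 1000 warmup + 1000 sampling iterations; every
parameter is monitored with split R-hat and an autocorrelation-based
effective sample size, and fits warn when any confusion mean or behavior
parameter exceeds R-hat 1.05. All chains are seeded deterministically from
the configuration seed, so runs are exactly reproducible. Scaled-down
settings (2 chains, hundreds of iterations) are used in the package's own
simulation studies; the problem sizes there — cohorts of 8–50 children,
2–3 recordings each, calibration sets of 160–300 windows — were chosen so
that full studies remain desk-scale while keeping the qualitative behavior
of the published-scale analyses.

### Checking interval calibration

`coverage_calibration()` validates the latent-count intervals in two
designs. The default fixes plausible generating values (the reference
conditions and a consistent classifier) and resimulates datasets around
them — the classical validation design, under which coverage is
approximately nominal wherever the latent counts are data-identified.
Passing a `coverage_prior()` switches to full simulation-based
calibration, redrawing all parameters from the fit's own priors each
time; in that mode exact nominal coverage is a theorem for a perfect
sampler, and residual under-coverage observed at desk-scale chain lengths
in the worst prior draws (Gamma shapes near 1, strong overdispersion) is
a direct, quantitative readout of the random-walk sampler's limits —
which is precisely what makes the mode useful as a stress diagnostic.
Because the latent counts are continuous while truths are integers,
interval checks apply a half-count continuity correction.

### What calibration can and cannot do

Calibration corrects aggregate counts and effect sizes within the assumed
behavior model; it does not relabel individual segments. The calibrated
posterior is wider than the naive one — the price of acknowledging that
many true-count configurations are compatible with the classifier output;
this trade of bias for variance is a design property, checked by the test
suite. Identification of confusion-sensitive effects (e.g. a sibling
effect on adult input when other-child speech leaks into adult classes)
comes from the calibration clips via the confusion profile; it degrades
gracefully but noticeably as clips become scarce or the classifier becomes
inconsistent across recordings (small Gamma shapes). With no calibration
clips at all the confusion posterior reproduces its prior.

## Sensitivity analysis instead of calibration

When full calibration is unnecessary, `run_sensitivity()` implements the
simulation loop: draw a true parameter value (or fix it at a null),
generate true counts, distort them through the confusion model (rates
redrawn per unit, since recording-level variability is part of the
mechanism being simulated), run the analysis pipeline on the distorted
counts, and compare. `female_proportion_experiment()` is the packaged
reference experiment: CHI fixed at 1500; OCH 0 or 1000 with equal
probability; FEM = 3000p and MAL = 3000(1-p) with p uniform — total adult
input fixed — over 2000 samples. Bias curves are summarized with a running
median/mean and central 80% band on a grid (half-width 0.05), a smoother
chosen for robustness at the grid edges. `null_test()` uses the add-one
Monte-Carlo p-value `(1 + #{null >= observed}) / (N + 1)`, which is never
zero and is uniform under the null up to discreteness.

## Numerical choices and degenerate inputs

- Zero means: `DPO(0, tau)` is a point mass at zero; confusion cells with
  `mu = 0` stay exactly zero in draws and likelihoods.
- The enumeration cap (40 per 15-s window) is an error, never a silent
  approximation.
- Correlations with a constant count column are reported as `NA` with a
  warning, never as zero; the ICC of degenerate data is `NA` likewise.
- The ICC is ICC(A,1) — two-way, absolute agreement, single rater — since
  absolute count estimates are being compared; other conventions exist and
  the mean-squares computation is small and explicit.
- Latent counts are sampled on the log scale (positivity by construction)
  and initialized by moment inversion — observed counts deflated by the
  clip-estimated recall — with chain starts overdispersed so that a shared
  starting basin cannot masquerade as a narrow posterior.
- Ages are validated non-negative; time-of-day and window intervals are
  half-open, so boundary segments are counted exactly once.

## Known limitations

- The additive-leakage assumption ignores overlapping speech; dense
  overlap would bias short-time-scale input-output couplings.
- Confusion rates are independent of covariates (age, environment); a
  classifier that hears older children better would masquerade as a
  developmental effect.
- Human annotations are treated as ground truth; annotator error and
  aggregation across annotators are out of scope.
- A single classifier is calibrated per fit; multi-classifier joint
  inference is out of scope (fits are compared post hoc).
- The component-wise sampler, even with ridge moves, needs visibly more
  iterations than a well-tuned gradient sampler would; the diagnostics are
  there to make this cost observable.
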