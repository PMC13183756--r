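# vocalib

Speaker diarization errors distort science built on vocalization counts.
vocalib is an R package for researchers who measure children's language
environments with automatic voice-type classifiers on long-form audio:
it models how a classifier's confusion between speaker classes (the key
child CHI, other children OCH, female adults FEM, male adults MAL)
propagates into downstream statistics, lets you *simulate* that distortion
for sensitivity analysis and null-hypothesis testing, and lets you *undo*
it by joint Bayesian calibration against a small set of human-annotated
clips.

## The model in brief

True counts `v_i` per recording are latent. Each true vocalization of
speaker `i` yields a double-Poisson number of detections attributed to
speaker `j`:

    n_ij ~ DPO(lambda_ij * v_i, tau),        n_j = sum_i n_ij

with per-recording confusion rates `lambda_kij ~ Gamma(shape alpha_ij,
mean mu_ij)`. On human-annotated 15-s windows the likelihood of `n` given
`v` marginalizes the latent decomposition exactly (computed as a
convolution); at the recording level `v` is treated as continuous with
`n_kj ~ DPO(sum_i lambda_kij v_ki, tau)`.

Speech behavior follows a hierarchical log-link GLM: population, corpus
and child levels; sibling effects on other-child and adult speech; random
child age slopes with a 24-month plateau; and a long-term effect of adult
input on child output. The joint posterior over behavior parameters,
confusion parameters and latent true counts is sampled with an adaptive
Metropolis-within-Gibbs sampler (compiled, with dedicated moves along the
posterior's slow ridges). `naive_fit()` is the uncalibrated comparator:
the same behavior model with classifier counts treated as truth.

See the methods vignette (`vignettes/calibration-methods.Rmd`) for the
full model, priors, numerical choices and limitations.

## Worked example

Simulate a cohort, distort it through a classifier profile, and compare
the naive and calibrated estimates of the sibling effect on adult input:

```r
library(vocalib)

par <- behavior_params()              # reference simulation conditions
prof <- bundled_profile("recall_biased")

truth <- simulate_true_counts(par, children = 50, recordings_per_child = 3,
                              seed = 1)
set.seed(2)
measured <- apply_classifier(truth, prof)
clips <- make_calibration_clips(fixture_spec(
  calib_recordings = 10, windows_per_recording = 20, profile = prof,
  seed = 3))

dataset <- list(recordings = measured, clips = clips)
naive <- naive_fit(dataset, mcmc = mcmc_config(2, 400, 400, seed = 4))
calib <- fit_joint(dataset, mcmc = mcmc_config(2, 450, 550, seed = 5))

summary(naive, params = "beta_sib_adu")
summary(calib, params = "beta_sib_adu")
```

With the seeds shown, the generating value is `beta_sib_adu = -0.22`; the
naive posterior is `-0.23` (SD `0.081`) and the calibrated posterior
`-0.27` (SD `0.10`). Under this mild, consistent classifier the naive fit
happens to be nearly unbiased and the two estimates agree — the calibrated
interval is wider, the price of admitting classifier stochasticity. The
payoff appears under stronger confusion: with other-child speech leaking
into the adult classes (the profile used in the reproduction script
below), the naive estimate of this effect collapses toward zero while the
calibrated one stays near the truth, beating the naive estimate in ~94%
of replicates at roughly two-thirds of its absolute error.

For measurement-level distortion, the packaged sensitivity experiment
reproduces the female-adult-proportion mechanism:

```r
res <- female_proportion_experiment(bundled_profile("precision_biased"),
                                    n_samples = 2000, seed = 1)
bias_curve(res)    # running mean/median and 80% band of measured vs true
```

Segment tables (RTTM or CSV), daytime filtering, 15-s windowing and count
tabulation live in `read_segments()`, `filter_time_of_day()`,
`window_counts()`, `recording_counts()` and `calibration_clips()`. A thin
command-line wrapper is provided in `exec/vocalib` (subcommands `synth`,
`counts`, `fit-confusion`, `calibrate`, `naive-fit`, `coverage`,
`sensitivity`, `null-test`).

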