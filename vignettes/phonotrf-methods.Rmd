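---
title: "Methods: forward TRF modeling of phonological-feature acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward TRF modeling of phonological-feature acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Infants acquire the phonemes of their native language during a period in
which their electrophysiology is dominated by slow activity, too slow to
resolve individual ~50 ms phonemes. Phonological *features* ([voiced],
[nasal], ...), however, often span several consecutive phonemes, so
different features alternate at very different time scales: in German
child-directed speech the median feature-continuous stretch ranges from
~68 ms ([lateral]) to ~228 ms ([voiced]). `phonotrf` implements an analysis
pipeline for testing whether the stability of the infant brain's response
to a feature — and its developmental trajectory — depends on that time
scale: continuous speech is annotated at the phoneme level, expanded into
binary feature step functions, and related to the continuous EEG through
forward encoding models (temporal response functions, TRFs), whose
cross-validated prediction accuracy serves as the index of feature
representation. A statistical layer of linear mixed models relates this
accuracy to age, language condition (native vs non-native), and feature
timing statistics.

## The TRF model

The forward model assumes the EEG at electrode $e$ is a lagged linear
functional of $P$ stimulus predictors $s_p(t)$ plus noise:

$$ y_e(t) = \sum_{p=1}^{P} \sum_{\ell = L_{\min}}^{L_{\max}}
   w_{p}^{(e)}(\ell)\, s_p(t - \ell) + \varepsilon_e(t), $$

with the lag window $[-150, 400]$ ms (negative lags let the model capture
activity preceding a feature onset). The kernel $w$ is estimated by ridge
regression on the lagged design matrix $X$:

$$ \hat w = (X^\top X + \lambda M)^{-1} X^\top y, \qquad
   M = \mathrm{mean}(\mathrm{diag}(X^\top X)) \cdot I . $$

Scaling the identity by the mean diagonal makes $\lambda$ unitless and
comparable across designs; columns are z-scored internally and
coefficients returned in original units. `ridge_fit()` implements the
solver; `trf()` is the user-facing constructor returning a classed object
with `coef`, `predict`, `plot`, `residuals` and `simulate` methods.

```{r}
library(phonotrf)
fit <- trf(predictors, eeg, lambda = 0.01, lag_window = c(-150, 400))
plot(fit, electrode = "FC5")
```

### Cross-validation and the permutation baseline

Reliability is quantified by 10-fold cross-validation over *contiguous
time blocks* (shuffled samples would leak information through the strong
autocorrelation of both EEG and step-function predictors; the literature
the pipeline follows is silent on fold geometry, so the conservative
choice is made). Per fold, the model is trained on 80% of the data, the
ridge parameter is selected by exhaustive search of
$\lambda \in 10^{-7} \dots 10^{7}$ (15 logarithmic steps) on a 10%
validation block, and Pearson's $r$ between predicted and observed EEG on
the held-out 10% test block is the fold's accuracy. Per-electrode accuracy
aggregates fold $r$ values by Fisher-z averaging (the correlation of
concatenated predictions is available via `aggregate = "concat"`). The
$\lambda$ search is fold-specific; a global-$\lambda$ variant would only
differ when folds are heterogeneous.

The chance level is estimated by a permutation baseline: per fold, the
predictor time axis is circularly shifted by a uniform random offset of at
least 5 s (circular shifts preserve all marginal and autocorrelation
statistics of the predictors while destroying their alignment with the
EEG) and the complete fit/score procedure is rerun. One shift per fold is
the default (`n_per_fold` raises it).

## Predictors

* **Feature step functions** — phoneme annotations (Praat TextGrid, long
  or short dialect, or 3-column TSV) are mapped through a phoneme-feature
  lexicon over the canonical 17 binary features and merged into
  feature-continuous stretches by `expand_features()`. A silence gap ends
  a stretch, and the silent interval up to the next phoneme onset is
  appended to the ending stretch's duration — silence introduces no new
  phonological information that would interrupt processing. Stretches are
  rasterized to 0/1 columns at the analysis rate.
* **Spectrogram** — 16 STFT band envelopes with log-spaced centers,
  250–8000 Hz, edges at geometric midpoints. A log-compression flag
  exists and defaults to off.
* **Pitch** — frame-based autocorrelation F0 tracking with parabolic peak
  refinement, search range 75–600 Hz, unvoiced frames set to 0.

The analysis sampling rate defaults to 100 Hz: comfortably above twice
the 10 Hz upper edge of the TRF band while keeping design matrices small.
The pitch-similarity statistic (`pitch_similarity()`) is defined as the
maximum absolute normalized cross-correlation between the z-scored feature
step function and the z-scored F0 track over lags within ±500 ms — the
prosodic (<4 Hz) scale; a zero-lag-only variant is available. The raw
(zeros-in-unvoiced) track is used by default; linear interpolation through
unvoiced frames is a documented option (`interpolate_unvoiced`).

## EEG preprocessing

The automated cleaning pipeline (`preprocess_recording()`) follows the
HAPPE lineage for infant data, at the native 500 Hz rate:

1. zero-phase FIR high-pass (order 1650, −6 dB at 0.5 Hz) and low-pass
   (order 332, −6 dB at 47.5 Hz);
2. bad-channel detection by three rules: flat for >30 s; R/S Hurst
   exponent <0.7 (the rescaled-range estimator over dyadic windows — the
   threshold is inherited from the pipeline this follows, the estimator is
   the classic one); average log power 1–100 Hz deviating >2.75 SD from
   the channel distribution (a robust median/MAD z is used so an extreme
   channel cannot mask itself). Power is computed on the high-passed but
   not low-passed signal, which the stage ordering implies, since
   1–100 Hz exceeds the low-pass band;
3. level-13 wavelet thresholding (coiflet-4, periodized orthogonal DWT):
   at each level the *suprathreshold excess* over the level-wise universal
   threshold is removed (coefficients clamped, i.e. the soft-thresholded
   artifact reconstruction is subtracted). This is the artifact-removal
   convention of the wavelet-enhanced pipelines this follows; removing the
   subthreshold part instead would delete band-limited oscillations;
4. spherical-spline interpolation of flagged channels (order 4, 50
   Legendre terms) at idealized 10/10 positions constructed from anchor
   10/20 angles plus spherical midpoints;
5. linked-mastoid re-referencing.

For TRF preparation, `epoch_reject_recombine()` band-passes 1–10 Hz
(zero-phase FIR, order set by a 0.5 Hz transition width), segments into
1-s epochs, drops epochs whose *unfiltered* amplitude exceeds ±200 μV on
any channel (the threshold is applied to the cleaned but not
band-filtered signal; which "unfiltered" stage the original procedure
used is ambiguous and this choice is documented here), and recombines
surviving epochs with 1 s of zeros at discontinuities. The inserted zeros
are flagged and excluded from accuracy computations — they are
deterministic, not data — but retained in the training rows, mirroring
the recombined stream. Participants/conditions retaining <350 s are
flagged excluded (75% of a 7.5-minute story).

## Group-level models

All mixed models use `lme4` with Satterthwaite degrees of freedom via
`lmerTest`; age is mean-centered; condition is coded native = −0.5,
non-native = +0.5. In order:

* `fit_condition_age_model()`:
  `r ~ age * condition + (1 | participant)`, with per-condition simple
  slopes obtained by refitting with the condition of interest at code 0
  (this reproduces the interaction test exactly and gives each slope its
  own Satterthwaite df; the df of follow-up tests therefore need not
  equal the interaction's 64-style df, which is reported as is).
* `divergence_age()`: per-participant accuracy differences (native −
  non-native, or observed − baseline) are regressed on age; the pointwise
  95% CI of the *conditional mean* (not a prediction interval) is
  evaluated on a 1-month grid and the first age whose lower bound exceeds
  zero is reported, or "none" (`NA`).
* `fit_feature_timing_model()`:
  `(r_obs − r_base) ~ age * duration_rank + occurrence_rank +
  (1 | feature) + (1 | participant)`. Random intercepts only — no random
  slopes — which matches the original specification; a known consequence
  (demonstrated in the tests) is anticonservative interaction tests when
  per-feature slope heterogeneity exists but is unrelated to the tested
  rank, so the type-I simulations are run under the no-heterogeneity null.
* `fit_pitch_similarity_model()`: adds `age * pitch_similarity_rank`,
  compares against the duration-only model by a likelihood-ratio test on
  maximum-likelihood refits (the standard requirement for LR tests on
  fixed effects), and reports fixed-effect variance inflation factors so a
  dissociation can be judged against collinearity.
* `balanced_bootstrap_ci()`: percentile 95% CIs of interaction-with-age
  t values over sex-balanced resamples (equal numbers of each sex, with
  replacement, totalling the original N), plus the fraction of resamples
  in which each term is significant.
* `compare_age_shapes()`: LR tests for log, quadratic and cubic age terms
  added to the linear model.

Ranks are kept on their raw 1–17 scale (not centered), as in the models
this layer mirrors; mean-centering age ensures interaction t values are
invariant to age-origin shifts (a tested invariant).

## The synthetic-data generator

No infant EEG or annotated story audio is distributed with the research
this package operationalizes, so every stage is validated against a
generator with known ground truth (`generator_config()` +
`generate_phoneme_stream()` / `generate_pitch()` / `simulate_eeg()` /
`generate_cohort()`).

**Phoneme stream.** Phoneme-sized slots with gamma-distributed durations
(mean 50 ms, shape 4 — child-directed speech runs at ~20 phonemes/s) and
occasional pauses (probability 0.06, 100–400 ms). Feature trajectories
are independent two-state Markov chains per feature; a slot's label *is*
its feature bundle, so annotation and lexicon are consistent by
construction (the labels are synthetic patterns, not German segments —
the shipped German SAMPA lexicon serves real annotations). On-state
persistence is calibrated iteratively against the realized,
silence-appended merged-run medians (common random numbers across
iterations, then a rejection step), so that the defaults reproduce the
reference table of `feature_timing_reference()` within 15%; feature
occupancy rises with occurrence rank (0.15–0.65). Targets shorter than
the mean phoneme are rejected as infeasible.

**Pitch.** A sum of slow random sinusoids (0.3–3.5 Hz — the <4 Hz
prosodic modulation scale) around 220 Hz, gated by the voiced-feature
mask; `pitch_coupling` blends in an independent mask for decoupling
experiments.

**EEG.** The forward model mirrors the estimator exactly: the driven
signal is the lagged design times the stacked kernels
(difference-of-gammas, peaking 100–250 ms — an infant-auditory-like
shape; recorded in the ground-truth attribute), scaled by a participant
gain, mixed across electrodes by a fixed exponential profile, plus 1/f
noise (the slow-dominated infant background; exponent 1, white optional)
scaled per electrode to the requested SNR. Artifact injection (spikes,
flat channels) supports preprocessing tests.

**Cohorts.** Two tiers. The *record level* (default) draws prediction
accuracies directly from an accuracy-scale model: baseline accuracy ~0,
native accuracy growing linearly with age and crossing the non-native
level at the configured crossover age (28 months by default; 14 months
for the baseline comparison), per-feature slopes tied linearly to
duration rank, pitch-similarity rank, or neither. Effect-size defaults —
r0 = 0.01, condition slope 1.5e-3 per month, residual SD 0.012,
participant SD 0.01, slope gradient 5e-5 per rank unit per month — are
on the accuracy scale of developmental speech-tracking studies but
deliberately strong enough that confidence-interval-based divergence
detection trails the true mean crossover by only a few months; they are
fixed once and all power/type-I figures in the tests are contracts at
these defaults. The *signal level* (`level = "signals"`) synthesizes
predictor streams and EEG per participant with age-dependent gains for
end-to-end tests. Every dataset carries its configuration and seed;
regeneration is bit-identical.

**Dissociation design.** When `decouple_ranks = TRUE`, the rank column
*not* driving the slopes is replaced by an independent permutation. This
matters: in the real reference table duration and pitch-similarity ranks
are strongly correlated, and no statistical procedure can dissociate
drivers that are almost collinear; the decoupled design is the
generator's analog of asking whether the model *would* attribute the
effect correctly if the two timescale variables disagreed.

## Numerical choices and problem sizes

* Ridge solves use an eigendecomposition of the standardized training
  Gram matrix per fold, shared across the λ grid; per-block sufficient
  statistics make the 10 folds a single pass over the design.
* Correlations on held-out blocks define `r = 0` when either side is
  constant (e.g. an all-zero prediction under extreme regularization).
* Rank ties break deterministically by the canonical feature order.
* Adjacency tolerance when merging feature runs is 1 ms — forced
  alignment output abuts exactly; the tolerance guards float noise.
* Validation problem sizes: kernel recovery runs at 400 s × 100 Hz ×
  4 features (SNR 10 dB); the null calibration at 120 s × 2 features ×
  50 replicates; cohort-level simulations use 200 replicates at n = 40–66
  participants. These sizes give stable Monte-Carlo estimates while
  keeping the full validation suite in the minutes range on one core.

## What passing tests do and do not show

The generator emulates the *timing statistics* of feature streams, the
linearity of the forward model, and 1/f noise. It does not emulate
coarticulation, correlated feature bundles of a real phoneme inventory
(features are independent chains), acoustic variability of real speech,
non-stationary artifacts beyond injected spikes, or volume-conduction
geometry beyond a fixed mixing profile. Passing contracts therefore
demonstrate that the estimators and the statistical layer are correct and
calibrated under the stated model — not that real infant EEG satisfies
that model. Known limitations: random-intercept-only feature models are
anticonservative under slope heterogeneity (see above); the divergence
age is a CI-based detection age and systematically trails the true mean
crossover as noise grows; and the spherical-spline montage uses idealized
positions, not digitized electrode locations.
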