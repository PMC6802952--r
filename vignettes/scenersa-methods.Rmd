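---
title: "Methods: spatiotemporally resolved RSA of fragmented scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporally resolved RSA of fragmented scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

During natural vision the brain receives incomplete fragments of scenes
and must contextualize them: fragments from the top of a scene (sky,
ceilings) play a different role than fragments from the bottom (ground,
floors). If the visual system sorts incoming information by such spatial
*schemata*, then neural responses to scene fragments — all presented at
central fixation, with no explicit location differences — should cluster
by the fragments' typical vertical position within their scene of
origin, over and above their scene category and low-level features.

`scenersa` implements the full analysis pipeline needed to test this:
representational dissimilarity matrices (RDMs) from fMRI-style voxel
patterns and EEG-style epoched sensor data, predictor-RDM regression
with feature-model residualization, and group-level inference resolved
over regions and time. A synthetic-data generator with planted
representational structure makes every stage testable end to end
without recorded data.

## The stimulus design

The default design crosses 6 scenes (3 indoor, 3 outdoor) with 6
fragment positions (3 vertical x 2 horizontal), giving 36 conditions.
`build_stimulus_set()` fixes the canonical condition order —
scene-major, then vertical (1 = top .. 3 = bottom), then horizontal
(1 = left, 2 = right) — and all RDMs, masks and pair vectors in the
package are index-aligned to it. The canonical *pair* order is the
column-major lower triangle of that condition order; with 36 conditions
there are `choose(36, 2) = 630` unordered pairs.

Three binary predictor RDMs code the hypotheses: vertical location
(0 = same level, 1 = different), horizontal location, and scene
category (0 = same scene of origin). A graded alternative,
`build_vertical_euclidean_rdm()`, codes vertical dissimilarity as the
absolute difference of ordinal levels. `build_cross_type_mask()`
restricts analyses to the 324 indoor-outdoor pairs; within that
restriction every same-scene pair is gone, so a category predictor
cannot be constructed (requesting one is an explicit error).

## Neural dissimilarity

**fMRI.** `crossval_corr_rdm()` computes, per condition pair, a
split-half cross-validated correlation difference. For every unordered
equal split of the runs (10 splits for 6 runs), condition patterns are
averaged within each half; within-condition correlations (condition
*i* in half 1 vs *i* in half 2, same for *j*) and between-condition
correlations (*i* vs *j*, both directions) are Fisher-transformed and
the dissimilarity is mean(within) − mean(between), averaged over
splits. The measure is zero in expectation for indistinguishable
conditions and positive for discriminable ones; individual entries may
be negative under noise, which is information the GLM stage should see,
so no rectification is applied. Patterns are first run-demeaned
(`demean_by_run()`), and trial patterns can be extracted from a volume
series by shifting the onset by 3 TRs (6 s hemodynamic delay,
sweepable 0–5) via `extract_trial_patterns()`.

Choices the definition leaves open, fixed here: both within- and both
between-correlations are averaged per split (this guarantees an exactly
symmetric RDM); Fisher transforms are applied per split before
averaging across splits; correlations are clipped to |r| ≤ 1 − 1e−12 so
noise-free data keeps finite transforms; zero-variance patterns yield
r = 0 with a warning rather than an error, so degenerate inputs cannot
abort a batch run.

**EEG.** `decode_series()` builds one 36 x 36 RDM per time point from
pairwise linear-discriminant decoding accuracies (chance 0.5), using
the channel values at a single sample as features. Cross-validation is
leave-one-trial-out with paired folds: fold *k* holds out trial *k* of
each of the two conditions, trains on the rest, and tests the held-out
trials, so every trial is tested exactly once and training sets stay
balanced. The pooled within-class covariance is shrunk toward the
scaled identity with a fixed coefficient (default 0.05, configurable);
with 17 channels and few trials a raw covariance can be singular, and
conclusions should not hinge on the exact value — the test suite
checks decoding behaviour at several coefficients. Decoding is fully
deterministic. Epochs are baseline-corrected per trial and channel and
downsampled by boxcar averaging (`preprocess_epochs()`); channel
subsets are selected by 10-10 name (`select_channels()`, default
posterior set of 17 sensors).

## Modelling the RDMs

`rdm_glm()` vectorizes an RDM into its canonical 630-pair vector,
z-scores the criterion (predictors stay in raw binary form — only the
neural side is standardized, so betas are comparable across subjects
and units while predictor units stay interpretable), and fits ordinary
least squares with an intercept. z-scoring rescales all betas by one
positive factor and leaves signs and t-statistics unchanged, which the
suite verifies. Under a pair mask, criterion and predictors alike are
restricted and the z-scoring uses retained entries only.

`run_glm_suite()` packages the four analyses: the full three-predictor
GLM; the feature-residualized GLM; the cross-type-restricted GLM
(vertical + horizontal only); and residualization followed by
restriction.

**Residualization.** To remove structure explained by a feature model
(e.g. the layer RDMs of a deep categorization network, built with
`layer_rdm()` as 1 − Pearson correlation of unit activations, or a
pixel-dissimilarity control), the covariate bank enters a first-stage
regression and the second stage models what remains. The package's
default is Frisch–Waugh-consistent: *both* the criterion and the
predictors of interest are residualized on the bank, which is
algebraically identical to one joint GLM with the bank as nuisance
regressors. Residualizing the criterion alone — also available, via
`residualize_predictors = FALSE` or the exported `rdm_residualize()` —
leaves the predictors' bank-correlated parts in place; because the
binary category and location RDMs are not mutually orthogonal over the
630 pairs, that variant biases the remaining betas by the projection
and cannot drive a fully-spanned predictor's beta exactly to zero. The
joint-model reading makes the intended contract exact: a predictor
fully explained by the bank is reported with beta 0 (with a warning),
and surviving predictors keep their planted effects untouched. On
noise-free data with a bank spanning the category RDM, the category
beta is 0 to machine precision while the planted vertical beta
survives — the deterministic signature the acceptance suite checks.

## Group-level inference

For region-resolved (fMRI-style) betas, `group_ttest()` performs
one-tailed one-sample t-tests against zero per unit (positive betas are
the direction of interest), with Bonferroni correction across regions
(`bonferroni_adjust()`, family size 3 for the OPA/PPA/V1 setting).

For time-resolved (EEG-style) betas, `sign_permutation_test()` combines
threshold-free cluster enhancement with a max-statistic sign-permutation
null:

* `tfce_1d()` enhances the group t-map:
  TFCE(t) = Σ<sub>h</sub> e(h,t)<sup>E</sup> · h<sup>H</sup> · dh, with
  E = 0.5, H = 2 and dh = max(t)/100 — the standard parameterization
  for cluster enhancement of statistic maps; connectivity is adjacent
  samples on the time axis (the electrode dimension is already
  collapsed by the decoder). Negative values contribute nothing
  (one-tailed use). The integration step is fixed from the observed map
  and reused for all permutation maps.
* Each of the (default 10,000) iterations flips the sign of each
  subject's whole beta time course independently, recomputes the t-map,
  enhances it, and records the maximum — family-wise error control by
  the max statistic. Observed enhanced values are converted to Z
  against the null maxima; the default is moment-based
  (empirical mean/SD), with an empirical-quantile option
  (`z_method = "quantile"`), and the two agree on conclusions in the
  suite's synthetic checks. Significance is Z > 1.64 (p < 0.05,
  one-tailed).
* Onset latency is the first sample of the earliest suprathreshold run;
  peak latency is the argmax of the group t-map.
  `latency_bootstrap()` resamples subjects with replacement,
  recomputes the corrected significance per draw, and reports
  percentile confidence intervals plus the rate of draws with no
  significant sample (undefined onset).

## The synthetic-data generator

`simulate_fmri()` and `simulate_eeg()` plant known representational
structure: per subject, unit-variance Gaussian components are drawn for
each vertical level, horizontal level, and scene, plus a
condition-unique component, and combined with the `ground_truth()`
weights into condition patterns (voxel patterns for fMRI, channel
topographies for EEG). Components are drawn per subject because the
analysis is entirely within-subject — patterns are never aligned across
participants. Trial noise is i.i.d. Gaussian. The EEG effect time
course is zero before the onset (default 50 ms), ramps linearly to a
peak (default 200 ms) and decays exponentially (time constant 300 ms),
mimicking the morphology of stimulus-evoked decoding time courses; with
a ramp, the first sample that carries any effect is one step after the
nominal onset, which is why accurate onset recovery lands one sample
late.

Default design constants mirror the emulated studies: 30 fMRI subjects,
6 runs x 4 repetitions per condition, 100 voxels; 20 EEG subjects, 40
repetitions, 17 posterior channels, epochs −200..800 ms at 200 Hz.
Default effect weights reflect the emulated findings — vertical (0.7)
and category (0.7) structure present, horizontal absent (0), a
condition-unique component (1) so all pairs are discriminable — with
trial noise SD 3 (fMRI, where four trials per run are averaged) and 1
(EEG). These weights are the generator's operating point: strong enough
that a 20-subject experiment detects the planted effects reliably,
weak enough that single-subject RDMs remain visibly noisy.

`simulate_features()` emulates a layered feature model: each layer
mixes a condition-unique component with per-scene prototypes, the
prototype share growing across layers up to `category_gradient`, so
layer RDMs correlate increasingly with the category RDM along the
hierarchy — the qualitative behaviour of categorization-trained
networks. Real feature extractors plug in through
`extract_feature_bank()`; the package deliberately ships no trained
weights.

What the generator does *not* emulate: haemodynamic convolution and
temporal autocorrelation, event overlap, sensor covariance structure,
eye movements and artifacts, or realistic effect sizes per se. Passing
tests therefore show the *pipeline* is correct and calibrated — they do
not certify performance on any particular recorded dataset.

## Validation simulations

The package ships its validation studies as functions, used by the test
suite and the acceptance script alike:

* `calibrate_null_ttests()` — 170 null fMRI experiments (5 subjects,
  12-condition reduced design, 16 voxels, 2 runs) give 510 predictor
  tests; the one-tailed rejection rate must sit at the nominal 5%
  within its binomial confidence interval.
* `calibrate_fwer()` — 100 null EEG experiments (10 subjects, 8
  channels, 4 repetitions, 30 samples) through the full decoding + GLM
  + TFCE/sign-permutation pipeline (1,000 iterations each); the
  family-wise error must not exceed 0.05 plus two standard errors.
* `recover_effects_fmri()` / `recover_effects_eeg()` — 50 experiments
  each at the generator's operating point (20 subjects; 100 voxels /
  17 channels; EEG on the 12-condition design with 6 repetitions and a
  −100..300 ms epoch at 50 Hz) must detect the planted vertical effect
  and not the absent horizontal effect in at least 90% of runs.
* `recover_onset_latency()` — high-SNR EEG experiments sampled at
  10 ms must recover a planted 100 ms onset within one sample.
* `residualization_signature()` — deterministic: on noise-free data,
  a bank spanning the category RDM drives the category beta to 0
  (< 1e−10) while the planted vertical beta survives.

The reduced problem sizes are the package's chosen simulation scale;
they exercise exactly the same code paths as full-scale analyses.

## Numerical and design choices, in one place

* Diagonals of all RDMs are stored as `NA` — undefined, never zero.
* Correlation clipping at |r| ≤ 1 − 1e−12 before the Fisher transform.
* Zero-variance vectors (patterns, activations, criteria) produce
  r = 0 / betas 0 with a warning, never a crash.
* LDA shrinkage: fixed coefficient toward the scaled identity,
  default 0.05.
* Classical (Torgerson) scaling is the metric MDS default: it is
  deterministic and robust to tied and zero dissimilarities, which
  decoding RDMs produce routinely; Kruskal's non-metric refinement is
  available (`nonmetric = TRUE`). Cross-validated RDMs are shifted by
  their minimum before MDS (dissimilarities must be non-negative);
  decoding RDMs are used as-is. Successive MDS frames are aligned by
  rigid Procrustes (rotation/reflection/translation, no scaling), which
  provably preserves within-frame distances.
* Sliding-window smoothing (`smooth_series()`, default 15 ms) uses
  truncated centered boxcars at the series edges; edge samples are
  therefore reweighted slightly and the entrywise series mean is
  preserved only up to O(window/length).
* Serialization is plain CSV plus JSON manifests (`run_pipeline()`
  writes betas, statistics, design and a provenance block containing
  the full configuration and seeds). Outputs are reconstructible
  bit-for-bit from configuration + seeds; provenance deliberately
  excludes wall-clock timestamps for that reason.
* Every stochastic stage requires an explicit seed; generators restore
  the caller's RNG state.

## Known limitations

* The generator's linear pattern-plus-noise model has no temporal
  autocorrelation or realistic noise covariance; calibration results on
  real data may differ.
* TFCE z-conversion uses the empirical null moments by default; for
  very small iteration counts the quantile method is preferable (a
  warning fires when the tail is poorly resolved).
* The cross-type restriction assumes both scene types are present;
  single-type designs degrade to an empty mask with a warning.
* MDS stress is reported but not minimized iteratively in the metric
  default; strongly non-Euclidean RDMs may be better served by the
  non-metric option.

```{r example}
library(scenersa)
set <- build_stimulus_set()
study <- simulate_fmri(set, n_subjects = 8, n_voxels = 80, seed = 1)
betas <- purrr::imap_dfr(study$subjects, function(arr, s) {
  nr <- crossval_corr_rdm(demean_by_run(arr))
  run_glm_suite(nr, set, "full") |> dplyr::mutate(subject = s)
})
betas |>
  dplyr::group_by(predictor) |>
  dplyr::group_modify(~ group_ttest(.x)) |>
  dplyr::ungroup() |>
  dplyr::mutate(p.adjusted = bonferroni_adjust(p.value, m = 3))
```
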