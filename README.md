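# scenersa

Spatiotemporally resolved representational similarity analysis (RSA) of
fragmented scene stimuli.

## What problem this solves

When people view small fragments of natural scenes, does the visual
system sort those fragments by their typical place within the scene —
their position in the spatial *schema* — even when every fragment is
shown at fixation? Answering this requires comparing the similarity
structure of neural responses against competing hypotheses: vertical
within-scene location, horizontal location, and scene category, while
controlling for visual features a categorization network would extract.

`scenersa` is an R package for neuroimaging researchers running exactly
this kind of analysis: it builds neural representational dissimilarity
matrices (RDMs) from multivoxel fMRI patterns and from time-resolved
EEG sensor data, regresses them on predictor RDMs, removes feature-model
structure by residualization, and performs group-level inference over
regions and time. A synthetic-data generator with planted
representational structure makes the entire pipeline testable without
access to recorded data.

## The method in brief

For a stimulus set of 36 conditions — 6 scenes (3 indoor, 3 outdoor)
× 6 fragments (3 vertical × 2 horizontal) — the pipeline computes, per
subject:

- **fMRI dissimilarity**: the split-half cross-validated correlation
  distance. For each unordered split of the runs into halves *A*, *B*
  (all 10 splits of 6 runs) and each condition pair (*i*, *j*):

      d(i, j) = mean[ z(r(A_i, B_i)), z(r(A_j, B_j)) ]
              − mean[ z(r(A_i, B_j)), z(r(A_j, B_i)) ]

  with Fisher-transformed Pearson correlations `z(r)`, averaged over
  splits; 0 in expectation for indistinguishable conditions.

- **EEG dissimilarity**: pairwise linear-discriminant (LDA) decoding
  accuracy per time point (chance 0.5), leave-one-trial-out
  cross-validated, with shrinkage-regularized pooled covariance —
  one 36 × 36 RDM per sample of the epoch.

- **RDM regression**: the vectorized neural RDM (630 pairs; z-scored)
  is modelled as `y = b_v · vertical + b_h · horizontal + b_c ·
  category + intercept`, optionally after residualizing against a bank
  of feature-model RDMs (e.g. network-layer RDMs, `1 − r` of unit
  activations) and/or restricted to the 324 cross-scene-type pairs.

- **Group inference**: one-tailed t-tests with Bonferroni correction
  across regions (fMRI); threshold-free cluster enhancement (TFCE,
  `E = 0.5, H = 2`) with max-statistic sign-permutation correction at
  `Z > 1.64` across time (EEG), plus bootstrap onset/peak latencies.

## Worked example

Simulate an 8-subject fMRI-style experiment with planted vertical and
category structure (the generator default — no horizontal effect), build
each subject's cross-validated RDM, fit the three-predictor GLM, and
test the betas at the group level:

```r
library(scenersa)

set <- build_stimulus_set()           # 36 conditions, canonical order
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
#> # A tibble: 3 × 7
#>   predictor  unit  estimate statistic    df       p.value    p.adjusted
#>   <chr>      <chr>    <dbl>     <dbl> <dbl>         <dbl>         <dbl>
#> 1 category   unit   1.32       19.3       7 0.000000126   0.000000379
#> 2 horizontal unit   0.00351     0.328     7 0.376         1
#> 3 vertical   unit   1.23       32.6       7 0.00000000330 0.00000000991
```

The planted vertical and category organizations are detected (mean
betas 1.23 and 1.32, both corrected p < 0.001); the absent horizontal
organization is not (beta ≈ 0.004, p = 0.38).

The EEG side works the same way, with time as the unit and
sign-permutation-corrected significance:

```r
eeg <- simulate_eeg(set, n_subjects = 6, n_reps = 8,
                    times = seq(-100, 400, 20), seed = 2)
eb <- purrr::imap_dfr(eeg$subjects, function(ds, s) {
  run_glm_suite(decode_series(preprocess_epochs(ds)), set, "full") |>
    dplyr::mutate(subject = s)
})
sm <- sign_permutation_test(
  dplyr::filter(eb, predictor == "vertical") |>
    dplyr::select(subject, time = unit, beta),
  n_iterations = 1000, seed = 3)
sm
#> <stat_map> 26 time points, 16 significant
#>   onset 80 ms, peak 120 ms (t = 10.07, n = 6)
```

Vertical-location information becomes corrected-significant from 80 ms
on — the planted effect time course starts at 50 ms — and `glance(sm)`
/ `tidy(sm)` return the latencies and the full per-sample table.
`autoplot(sm)`, `plot_betas()`, `mds_series()` and `mds_movie()` cover
visualization, including the time-resolved multidimensional-scaling
movie of an RDM series. `run_pipeline(default_config(seed = 1),
out_dir)` drives the whole chain (simulation → RDMs → GLM suite →
statistics) and writes CSV results plus a JSON provenance block; a thin
command-line wrapper lives at `inst/cli/scenersa.R`.

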