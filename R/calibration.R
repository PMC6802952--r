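# Simulation studies validating the pipeline end to end: null
# calibration, family-wise error control, and parameter recovery. These
# run the same code paths a real analysis uses, on generated data whose
# ground truth is known.

derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1, n))
}

#' Null calibration of the group t-test on GLM betas
#'
#' Simulates fMRI-style experiments with zero planted effects, runs the
#' full per-subject pipeline (cross-validated RDM, three-predictor GLM)
#' and the one-tailed group t-test on every predictor, and reports the
#' rejection rate at `alpha`. Under the null this should sit at the
#' nominal level.
#'
#' @param n_sims Number of simulated experiments (3 predictor tests
#'   each).
#' @param n_subjects,n_voxels,n_runs Per-experiment design.
#' @param set Stimulus set (default: a 12-condition reduced design, which
#'   keeps the simulation cheap without changing the tested logic).
#' @param alpha Nominal test level.
#' @param seed Integer seed.
#' @return A list: `rate` (observed rejection rate), `n_tests`,
#'   `alpha`.
#' @export
calibrate_null_ttests <- function(n_sims = 170, n_subjects = 5,
                                  n_voxels = 16, n_runs = 2,
                                  set = build_stimulus_set(1, 3, 2),
                                  alpha = 0.05, seed) {
  seeds <- derive_seeds(seed, n_sims)
  null_truth <- ground_truth(0, 0, 0, 0, noise_sd = 1)
  pvals <- purrr::map(seeds, function(s) {
    study <- simulate_fmri(set, n_subjects, n_voxels, n_runs,
                           truth = null_truth, seed = s)
    betas <- purrr::imap_dfr(study$subjects, function(arr, subj) {
      run_glm_suite(crossval_corr_rdm(demean_by_run(arr)), set, "full") |>
        dplyr::mutate(subject = subj)
    })
    betas |>
      dplyr::group_by(.data$predictor) |>
      dplyr::group_map(~ group_ttest(.x)$p.value)
  })
  pvals <- unlist(pvals)
  list(rate = mean(pvals < alpha), n_tests = length(pvals), alpha = alpha)
}

#' Family-wise error of the TFCE + sign-permutation pipeline
#'
#' Simulates EEG-style experiments with zero planted effects, runs the
#' full pipeline (decoding RDM series, GLM, TFCE + sign-permutation
#' correction on the vertical-location betas) and reports the fraction
#' of experiments with any significant time point — the family-wise
#' error rate, nominally at most 0.05 for `threshold_z = 1.64`.
#'
#' @param n_experiments Number of simulated experiments.
#' @param n_permutations Sign-flip iterations per experiment.
#' @param n_subjects,n_channels,n_reps,times Per-experiment design
#'   (reduced scale by default).
#' @param set Stimulus set.
#' @param threshold_z Significance threshold.
#' @param seed Integer seed.
#' @return A list: `fwer`, `n_experiments`.
#' @export
calibrate_fwer <- function(n_experiments = 100, n_permutations = 1000,
                           n_subjects = 10, n_channels = 8, n_reps = 4,
                           times = seq(-45, 100, by = 5),
                           set = build_stimulus_set(1, 3, 2),
                           threshold_z = 1.64, seed) {
  seeds <- derive_seeds(seed, 2 * n_experiments)
  null_truth <- ground_truth(0, 0, 0, 0, noise_sd = 1)
  any_sig <- vapply(seq_len(n_experiments), function(e) {
    study <- simulate_eeg(set, n_subjects, n_channels, n_reps, times,
                          truth = null_truth, seed = seeds[e])
    betas <- purrr::imap_dfr(study$subjects, function(ds, subj) {
      run_glm_suite(decode_series(ds), set, "full") |>
        dplyr::mutate(subject = subj)
    })
    B <- as_beta_matrix(
      dplyr::filter(betas, .data$predictor == "vertical"))
    sm <- suppressWarnings(
      sign_permutation_test(B, times = times,
                            n_iterations = n_permutations,
                            threshold_z = threshold_z,
                            seed = seeds[n_experiments + e]))
    any(sm$table$significant)
  }, logical(1))
  list(fwer = mean(any_sig), n_experiments = n_experiments)
}

#' Recovery of planted fMRI effects
#'
#' Simulates fMRI experiments with a planted vertical-location and
#' scene-category organization and no horizontal effect (the generator
#' default), runs the full pipeline, and reports how often the group
#' test detects the vertical effect (one-tailed p < `alpha`) while the
#' horizontal effect stays non-significant.
#'
#' @param n_sims Number of simulated experiments.
#' @param n_subjects,n_voxels,n_runs,n_reps_per_run Per-experiment
#'   design (defaults: 20 subjects, 100 voxels, study run structure).
#' @param set Stimulus set (default: the full 36-condition design).
#' @param truth A [ground_truth()].
#' @param alpha Test level.
#' @param seed Integer seed.
#' @return A list of rates: `vertical_sig`, `horizontal_sig`,
#'   `success` (vertical significant and horizontal not), and `n_sims`.
#' @export
recover_effects_fmri <- function(n_sims = 50, n_subjects = 20,
                                 n_voxels = 100, n_runs = 6,
                                 n_reps_per_run = 4,
                                 set = build_stimulus_set(),
                                 truth = ground_truth(), alpha = 0.05,
                                 seed) {
  seeds <- derive_seeds(seed, n_sims)
  res <- purrr::map_dfr(seeds, function(s) {
    study <- simulate_fmri(set, n_subjects, n_voxels, n_runs,
                           n_reps_per_run, truth, seed = s)
    betas <- purrr::imap_dfr(study$subjects, function(arr, subj) {
      run_glm_suite(crossval_corr_rdm(demean_by_run(arr)), set, "full") |>
        dplyr::mutate(subject = subj)
    })
    tst <- betas |>
      dplyr::group_by(.data$predictor) |>
      dplyr::group_modify(~ group_ttest(.x)) |>
      dplyr::ungroup()
    tibble::tibble(
      vertical = tst$p.value[tst$predictor == "vertical"] < alpha,
      horizontal = tst$p.value[tst$predictor == "horizontal"] < alpha
    )
  })
  list(vertical_sig = mean(res$vertical),
       horizontal_sig = mean(res$horizontal),
       success = mean(res$vertical & !res$horizontal),
       n_sims = n_sims)
}

#' Recovery of planted EEG effects
#'
#' Simulates EEG experiments with a planted vertical-location effect and
#' no horizontal effect, runs decoding, GLM and the TFCE +
#' sign-permutation correction, and reports how often vertical location
#' reaches corrected significance somewhere in the epoch while
#' horizontal location does not.
#'
#' @param n_sims Number of simulated experiments.
#' @param n_subjects,n_channels,n_reps,times Per-experiment design
#'   (defaults: 20 subjects, the 17 posterior channels, reduced epoch).
#' @param set Stimulus set (default: 12-condition reduced design).
#' @param truth A [ground_truth()].
#' @param n_permutations,threshold_z Correction parameters.
#' @param seed Integer seed.
#' @return A list of rates: `vertical_sig`, `horizontal_sig`,
#'   `success`, `n_sims`.
#' @export
recover_effects_eeg <- function(n_sims = 50, n_subjects = 20,
                                n_channels = 17, n_reps = 6,
                                times = seq(-100, 300, by = 20),
                                set = build_stimulus_set(1, 3, 2),
                                truth = ground_truth(noise_sd = 1),
                                n_permutations = 500, threshold_z = 1.64,
                                seed) {
  seeds <- derive_seeds(seed, 3 * n_sims)
  res <- purrr::map_dfr(seq_len(n_sims), function(k) {
    study <- simulate_eeg(set, n_subjects, n_channels, n_reps, times,
                          truth, seed = seeds[k])
    betas <- purrr::imap_dfr(study$subjects, function(ds, subj) {
      run_glm_suite(decode_series(ds), set, "full") |>
        dplyr::mutate(subject = subj)
    })
    sig_any <- function(pred, s) {
      B <- as_beta_matrix(dplyr::filter(betas, .data$predictor == pred))
      sm <- suppressWarnings(
        sign_permutation_test(B, times = times,
                              n_iterations = n_permutations,
                              threshold_z = threshold_z, seed = s))
      any(sm$table$significant)
    }
    tibble::tibble(vertical = sig_any("vertical", seeds[n_sims + k]),
                   horizontal = sig_any("horizontal", seeds[2 * n_sims + k]))
  })
  list(vertical_sig = mean(res$vertical),
       horizontal_sig = mean(res$horizontal),
       success = mean(res$vertical & !res$horizontal),
       n_sims = n_sims)
}

#' Onset-latency recovery at high signal-to-noise ratio
#'
#' Plants a vertical-location effect whose time course starts at a known
#' onset, runs the EEG pipeline at high SNR, and reports the estimated
#' onset (first corrected-significant sample) per simulation. With a
#' linear ramp starting at the onset, the first sample carrying any
#' effect is one step later, so accurate recovery lands within one
#' sample of the planted onset.
#'
#' @param n_sims Number of simulated experiments.
#' @param onset_ms Planted onset.
#' @param times Epoch (default 10 ms resolution around the onset).
#' @param n_subjects,n_channels,n_reps Per-experiment design.
#' @param set Stimulus set.
#' @param n_permutations Correction iterations.
#' @param seed Integer seed.
#' @return A list: `onsets_ms` per simulation, `median_onset_ms`,
#'   `onset_ms` (planted), `step_ms`.
#' @export
recover_onset_latency <- function(n_sims = 5, onset_ms = 100,
                                  times = seq(-100, 300, by = 10),
                                  n_subjects = 12, n_channels = 17,
                                  n_reps = 8,
                                  set = build_stimulus_set(1, 3, 2),
                                  n_permutations = 500, seed) {
  seeds <- derive_seeds(seed, 2 * n_sims)
  truth <- ground_truth(vertical = 4, horizontal = 0, category = 0.5,
                        unique = 0.2, noise_sd = 0.4,
                        eeg_onset_ms = onset_ms, eeg_peak_ms = onset_ms + 100)
  onsets <- vapply(seq_len(n_sims), function(k) {
    study <- simulate_eeg(set, n_subjects, n_channels, n_reps, times,
                          truth, seed = seeds[k])
    betas <- purrr::imap_dfr(study$subjects, function(ds, subj) {
      run_glm_suite(decode_series(ds), set, "full") |>
        dplyr::mutate(subject = subj)
    })
    B <- as_beta_matrix(dplyr::filter(betas, .data$predictor == "vertical"))
    sm <- suppressWarnings(
      sign_permutation_test(B, times = times,
                            n_iterations = n_permutations,
                            seed = seeds[n_sims + k]))
    sm$onset_ms
  }, numeric(1))
  list(onsets_ms = onsets, median_onset_ms = stats::median(onsets),
       planted_onset_ms = onset_ms, step_ms = diff(times)[1])
}

#' Deterministic residualization signature on noise-free data
#'
#' Generates noise-free fMRI data with planted vertical and category
#' structure, builds the neural RDM, and runs the residualized GLM with
#' a covariate bank that spans the category RDM (the binary category RDM
#' plus simulated feature-layer RDMs). The category beta is annihilated
#' exactly while the planted vertical effect survives — the qualitative
#' signature of feature-model residualization sparing schematic coding.
#'
#' @param set Stimulus set.
#' @param n_voxels Voxels in the noise-free pattern.
#' @param seed Integer seed.
#' @return A list: `category_beta_abs`, `vertical_beta`,
#'   `full_category_beta` (pre-residualization, for contrast).
#' @export
residualization_signature <- function(set = build_stimulus_set(),
                                      n_voxels = 80, seed) {
  seeds <- derive_seeds(seed, 2)
  truth <- ground_truth(vertical = 1, horizontal = 0, category = 1,
                        unique = 1, noise_sd = 0)
  study <- simulate_fmri(set, n_subjects = 1, n_voxels = n_voxels,
                         n_runs = 2, truth = truth, seed = seeds[1])
  nr <- crossval_corr_rdm(demean_by_run(study$subjects[[1]]))
  bank <- c(list(category = build_category_rdm(set)),
            bank_rdms(simulate_features(set, n_layers = 4, layer_sizes = 40,
                                        category_gradient = 0.9,
                                        seed = seeds[2])))
  full <- run_glm_suite(nr, set, "full")
  resid <- suppressWarnings(
    run_glm_suite(nr, set, "dnn_resid", covariates = bank))
  list(
    category_beta_abs = abs(resid$beta[resid$predictor == "category"]),
    vertical_beta = resid$beta[resid$predictor == "vertical"],
    full_category_beta = full$beta[full$predictor == "category"]
  )
}
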