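#' Ground truth for the synthetic-data generators
#'
#' Bundles the planted effect weights and noise model used by
#' [simulate_fmri()] and [simulate_eeg()]. Weights scale subject-specific
#' random components shared by all conditions with the same vertical
#' level, horizontal level, or scene of origin; `unique` scales a
#' condition-specific component that makes every condition discriminable
#' from every other (the analogue of stimulus-driven idiosyncratic
#' responses). Setting every weight to 0 yields pure-noise data.
#'
#' Defaults mirror the empirical findings the generators emulate: a
#' vertical-location and a scene-category organization are present, a
#' horizontal organization is absent. The EEG effect time course is zero
#' before `eeg_onset_ms`, ramps linearly to its peak at `eeg_peak_ms`,
#' then decays exponentially with time constant `eeg_decay_ms`,
#' mimicking the morphology of stimulus-evoked decoding time courses.
#'
#' @param vertical,horizontal,category,unique Non-negative effect weights.
#' @param noise_sd Trial-level Gaussian noise standard deviation
#'   (arbitrary units, relative to unit-variance effect components).
#' @param eeg_onset_ms,eeg_peak_ms,eeg_decay_ms Effect time-course
#'   parameters (ms).
#' @return A list with class `ground_truth`.
#' @export
ground_truth <- function(vertical = 0.7, horizontal = 0, category = 0.7,
                         unique = 1, noise_sd = 3,
                         eeg_onset_ms = 50, eeg_peak_ms = 200,
                         eeg_decay_ms = 300) {
  w <- c(vertical = vertical, horizontal = horizontal, category = category,
         unique = unique)
  if (any(w < 0) || noise_sd < 0) {
    stop("effect weights and noise_sd must be non-negative", call. = FALSE)
  }
  if (eeg_peak_ms <= eeg_onset_ms) {
    stop("eeg_peak_ms must lie after eeg_onset_ms", call. = FALSE)
  }
  structure(list(weights = w, noise_sd = noise_sd,
                 eeg_onset_ms = eeg_onset_ms, eeg_peak_ms = eeg_peak_ms,
                 eeg_decay_ms = eeg_decay_ms),
            class = "ground_truth")
}

#' Evaluate the planted EEG effect time course
#'
#' @param truth A [ground_truth()].
#' @param times_ms Numeric vector of time points (ms).
#' @return Numeric vector in `[0, 1]`: 0 before onset, linear ramp to 1 at
#'   the peak, exponential decay after it.
#' @export
effect_time_course <- function(truth, times_ms) {
  on <- truth$eeg_onset_ms
  pk <- truth$eeg_peak_ms
  a <- ifelse(times_ms <= on, 0,
              ifelse(times_ms <= pk, (times_ms - on) / (pk - on),
                     exp(-(times_ms - pk) / truth$eeg_decay_ms)))
  a
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed) || !is.finite(seed)) {
    stop("an explicit integer `seed` is required", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Subject-specific unit-variance spatial components for each design factor.
# Returns a condition x n_units matrix of noiseless condition patterns.
condition_patterns <- function(set, n_units, weights) {
  n_cond <- nrow(set)
  comp <- function(groups) {
    u <- matrix(stats::rnorm(length(unique(groups)) * n_units),
                nrow = length(unique(groups)))
    u[match(groups, unique(groups)), , drop = FALSE]
  }
  weights["vertical"] * comp(set$vertical) +
    weights["horizontal"] * comp(set$horizontal) +
    weights["category"] * comp(set$scene_id) +
    weights["unique"] * matrix(stats::rnorm(n_cond * n_units), nrow = n_cond)
}

#' Simulate a multi-subject fMRI-style pattern dataset
#'
#' For each subject, draws noiseless condition patterns as a weighted sum
#' of a shared per-vertical-level component, per-horizontal-level
#' component, per-scene component, and a condition-unique component (all
#' unit-variance Gaussian across voxels, drawn independently per subject),
#' then adds i.i.d. Gaussian trial noise and averages the
#' `n_reps_per_run` trials of each condition within each run. This
#' emulates a design of identical runs in which every condition appears
#' several times per run.
#'
#' @param set A stimulus set from [build_stimulus_set()].
#' @param n_subjects Number of subjects (study default 30).
#' @param n_voxels Number of voxels in the simulated region.
#' @param n_runs Number of runs (must be >= 2; study default 6).
#' @param n_reps_per_run Trials per condition per run (study default 4).
#' @param truth A [ground_truth()].
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   data.
#' @return A list with class `fmri_study`: `subjects` (list of
#'   condition x run x voxel arrays), plus `set`, `truth`, and design
#'   constants.
#' @export
simulate_fmri <- function(set, n_subjects = 30, n_voxels = 100, n_runs = 6,
                          n_reps_per_run = 4, truth = ground_truth(), seed) {
  assert_stimulus_set(set)
  if (n_runs < 2) {
    stop("design error: n_runs must be >= 2 (split-half cross-validation)",
         call. = FALSE)
  }
  n_cond <- nrow(set)
  subjects <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      pat <- condition_patterns(set, n_voxels, truth$weights)
      arr <- array(NA_real_, dim = c(n_cond, n_runs, n_voxels))
      for (r in seq_len(n_runs)) {
        noise <- matrix(stats::rnorm(n_cond * n_voxels,
                                     sd = truth$noise_sd / sqrt(n_reps_per_run)),
                        nrow = n_cond)
        arr[, r, ] <- pat + noise
      }
      arr
    })
  })
  structure(list(subjects = subjects, set = set, truth = truth,
                 n_runs = n_runs, n_reps_per_run = n_reps_per_run,
                 seed = seed),
            class = "fmri_study")
}

#' @export
print.fmri_study <- function(x, ...) {
  d <- dim(x$subjects[[1]])
  cat(sprintf(
    "<fmri_study> %d subjects, %d conditions x %d runs x %d voxels (seed %d)\n",
    length(x$subjects), d[1], d[2], d[3], x$seed))
  invisible(x)
}

#' Simulate a multi-subject epoched EEG-style dataset
#'
#' For each subject, draws channel topographies for the vertical,
#' horizontal, scene-category and condition-unique design components and
#' injects them with the planted effect time course of `truth`
#' (zero pre-stimulus, ramp to a peak, decay; see [effect_time_course()]),
#' plus i.i.d. Gaussian sensor noise on every trial, channel and sample.
#'
#' @param set A stimulus set from [build_stimulus_set()].
#' @param n_subjects Number of subjects (study default 20).
#' @param n_channels Number of channels; 17 (the default) uses the
#'   posterior 10-10 channel names of [posterior_channels()].
#' @param n_reps Trials per condition (study default 40; must be >= 2 for
#'   leave-one-trial-out decoding).
#' @param times Time axis in ms; must include pre-stimulus samples
#'   (default -200..800 ms in 5 ms steps, i.e. 200 Hz).
#' @param truth A [ground_truth()]; its `noise_sd` is interpreted on the
#'   same arbitrary scale as the unit-variance topographies.
#' @param seed Integer seed.
#' @return A list with class `eeg_study`: `subjects` is a list of
#'   `eeg_dataset` objects (fields `epochs` trial x channel x time,
#'   `labels`, `times`, `sfreq`, `channels`).
#' @export
simulate_eeg <- function(set, n_subjects = 20, n_channels = 17, n_reps = 40,
                         times = seq(-200, 800, by = 5),
                         truth = ground_truth(noise_sd = 1), seed) {
  assert_stimulus_set(set)
  if (n_reps < 2) {
    stop("design error: n_reps must be >= 2 (leave-one-trial-out)",
         call. = FALSE)
  }
  if (!any(times < 0)) {
    stop("times must include pre-stimulus samples (baseline correction)",
         call. = FALSE)
  }
  steps <- diff(times)
  if (max(abs(steps - steps[1])) > 1e-9) {
    stop("times must be uniformly spaced", call. = FALSE)
  }
  channels <- if (n_channels == 17) posterior_channels() else
    sprintf("Ch%02d", seq_len(n_channels))
  n_cond <- nrow(set)
  n_time <- length(times)
  a <- effect_time_course(truth, times)
  subjects <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      topo <- condition_patterns(set, n_channels, truth$weights) # cond x ch
      labels <- rep(seq_len(n_cond), each = n_reps)
      n_trials <- length(labels)
      epochs <- array(stats::rnorm(n_trials * n_channels * n_time,
                                   sd = truth$noise_sd),
                      dim = c(n_trials, n_channels, n_time))
      for (t in which(a > 0)) {
        epochs[, , t] <- epochs[, , t] + a[t] * topo[labels, , drop = FALSE]
      }
      structure(list(epochs = epochs, labels = labels, times = times,
                     sfreq = 1000 / steps[1], channels = channels),
                class = "eeg_dataset")
    })
  })
  structure(list(subjects = subjects, set = set, truth = truth, seed = seed),
            class = "eeg_study")
}

#' @export
print.eeg_study <- function(x, ...) {
  d <- dim(x$subjects[[1]]$epochs)
  cat(sprintf(
    "<eeg_study> %d subjects, %d trials x %d channels x %d samples @ %g Hz (seed %d)\n",
    length(x$subjects), d[1], d[2], d[3], x$subjects[[1]]$sfreq, x$seed))
  invisible(x)
}

#' @export
print.eeg_dataset <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_dataset> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  invisible(x)
}

#' Simulate a bank of layered feature-model activations
#'
#' Stands in for activations extracted from a deep network: each layer's
#' unit activations mix a condition-unique component with a per-scene
#' prototype component. The prototype share grows linearly across layers
#' from 0 to `category_gradient`, so the correlation between each layer's
#' RDM and the binary category RDM increases along the hierarchy. With
#' `category_gradient = 1` the final layer is noise-free per-scene
#' prototypes, whose RDM is rank-equivalent to the category RDM.
#'
#' @param set A stimulus set from [build_stimulus_set()].
#' @param n_layers Number of layers (study analogue: 18).
#' @param layer_sizes Units per layer (recycled to `n_layers`).
#' @param category_gradient Final-layer prototype share in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with class `feature_bank`: `layers` is a named list of
#'   condition x unit activation matrices in hierarchy order.
#' @export
simulate_features <- function(set, n_layers = 18, layer_sizes = 200,
                              category_gradient = 0.8, seed) {
  assert_stimulus_set(set)
  if (n_layers < 1) stop("n_layers must be >= 1", call. = FALSE)
  if (category_gradient < 0 || category_gradient > 1) {
    stop("category_gradient must lie in [0, 1]", call. = FALSE)
  }
  sizes <- rep_len(layer_sizes, n_layers)
  n_cond <- nrow(set)
  g <- if (n_layers == 1) category_gradient else
    category_gradient * (seq_len(n_layers) - 1) / (n_layers - 1)
  layers <- with_seed(seed, {
    out <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      proto <- matrix(stats::rnorm(length(unique(set$scene_id)) * sizes[l]),
                      nrow = length(unique(set$scene_id)))
      uniq <- matrix(stats::rnorm(n_cond * sizes[l]), nrow = n_cond)
      out[[l]] <- sqrt(1 - g[l]^2) * uniq +
        g[l] * proto[match(set$scene_id, unique(set$scene_id)), , drop = FALSE]
    }
    names(out) <- sprintf("layer%02d", seq_len(n_layers))
    out
  })
  structure(list(layers = layers, set = set, category_gradient = category_gradient,
                 seed = seed),
            class = "feature_bank")
}

#' @export
print.feature_bank <- function(x, ...) {
  cat(sprintf("<feature_bank> %d layers, %d conditions, %s units\n",
              length(x$layers), nrow(x$layers[[1]]),
              paste(unique(vapply(x$layers, ncol, 1L)), collapse = "/")))
  invisible(x)
}
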