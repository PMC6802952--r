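# Pipeline driver, configuration handling and dataset subsetting.

#' Default pipeline configuration
#'
#' A complete, explicit configuration for [run_pipeline()], at a small
#' demonstration scale. Every stochastic stage carries its own seed.
#'
#' @param seed Base seed; stage seeds are derived deterministically.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    design = list(n_scenes_per_type = 3, n_vertical = 3, n_horizontal = 2),
    truth = list(vertical = 0.7, horizontal = 0, category = 0.7,
                 unique = 1, noise_sd_fmri = 3, noise_sd_eeg = 1,
                 eeg_onset_ms = 50, eeg_peak_ms = 200, eeg_decay_ms = 300),
    fmri = list(enabled = TRUE, n_subjects = 8, n_voxels = 60, n_runs = 4,
                n_reps_per_run = 4, tr_shift = 3, seed = seed + 11),
    eeg = list(enabled = TRUE, n_subjects = 8, n_channels = 17, n_reps = 8,
               time_start = -100, time_end = 400, time_step = 20,
               shrinkage = 0.05, seed = seed + 23),
    features = list(n_layers = 6, layer_sizes = 80, category_gradient = 0.9,
                    seed = seed + 31),
    glm = list(analyses = c("full", "dnn_resid", "cross_type", "combined"),
               residualize_predictors = TRUE),
    stats = list(n_iterations = 1000, threshold_z = 1.64, seed = seed + 47),
    viz = list(mds = FALSE, window_ms = 15)
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Missing fields are filled from [default_config()]; the configuration
#' round-trips losslessly through serialization.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  base <- default_config()
  cfg <- utils::modifyList(base, cfg)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  for (stage in c("fmri", "eeg", "features", "stats")) {
    if (is.null(cfg[[stage]]$seed) || !is.finite(cfg[[stage]]$seed)) {
      stop(sprintf("config validation error: stage '%s' has no seed", stage),
           call. = FALSE)
    }
  }
  invisible(cfg)
}

stage_try <- function(stage, unit, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed at %s: %s", stage, unit,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes simulate (fMRI and/or EEG, plus feature bank), RDM
#' construction, the GLM suite, and group statistics, writing flat CSV
#' results plus a JSON provenance block (configuration, seeds, package
#' version) into `out_dir`. Rerunning an identical configuration yields
#' bit-identical outputs.
#'
#' @param config Configuration list, see [default_config()] /
#'   [read_run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Invisibly, a result bundle: the studies, per-subject betas,
#'   and group statistics per analysis.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  validate_config(config)
  tr <- config$truth
  set <- stage_try("design", "stimulus set", build_stimulus_set(
    config$design$n_scenes_per_type, config$design$n_vertical,
    config$design$n_horizontal))
  truth_fmri <- ground_truth(tr$vertical, tr$horizontal, tr$category,
                             tr$unique, tr$noise_sd_fmri,
                             tr$eeg_onset_ms, tr$eeg_peak_ms, tr$eeg_decay_ms)
  truth_eeg <- ground_truth(tr$vertical, tr$horizontal, tr$category,
                            tr$unique, tr$noise_sd_eeg,
                            tr$eeg_onset_ms, tr$eeg_peak_ms, tr$eeg_decay_ms)
  bank <- stage_try("features", "simulate", simulate_features(
    set, config$features$n_layers, config$features$layer_sizes,
    config$features$category_gradient, seed = config$features$seed))
  covs <- bank_rdms(bank)
  bundle <- list(set = set, config = config)

  if (isTRUE(config$fmri$enabled)) {
    fmri <- stage_try("simulate", "fmri", simulate_fmri(
      set, config$fmri$n_subjects, config$fmri$n_voxels, config$fmri$n_runs,
      config$fmri$n_reps_per_run, truth_fmri, seed = config$fmri$seed))
    fmri_betas <- purrr::imap_dfr(fmri$subjects, function(arr, s) {
      nr <- stage_try("rdm-fmri", sprintf("subject %d", s),
                      crossval_corr_rdm(demean_by_run(arr)))
      purrr::map_dfr(config$glm$analyses, function(a) {
        stage_try("glm", sprintf("subject %d / %s", s, a),
                  run_glm_suite(nr, set, analysis = a, covariates = covs,
                                residualize_predictors =
                                  config$glm$residualize_predictors)) |>
          dplyr::mutate(subject = s, .before = 1)
      })
    })
    fmri_stats <- fmri_betas |>
      dplyr::group_by(.data$analysis, .data$predictor) |>
      dplyr::group_modify(function(d, key) {
        group_ttest(dplyr::mutate(d, unit = "roi"))
      }) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$analysis) |>
      dplyr::mutate(p.adjusted = bonferroni_adjust(
        .data$p.value, m = dplyr::n())) |>
      dplyr::ungroup()
    bundle$fmri <- list(study = fmri, betas = fmri_betas, stats = fmri_stats)
  }

  if (isTRUE(config$eeg$enabled)) {
    eeg <- stage_try("simulate", "eeg", simulate_eeg(
      set, config$eeg$n_subjects, config$eeg$n_channels, config$eeg$n_reps,
      times = seq(config$eeg$time_start, config$eeg$time_end,
                  by = config$eeg$time_step),
      truth_eeg, seed = config$eeg$seed))
    eeg_betas <- purrr::imap_dfr(eeg$subjects, function(ds, s) {
      ser <- stage_try("rdm-eeg", sprintf("subject %d", s),
                       decode_series(preprocess_epochs(ds),
                                     shrinkage = config$eeg$shrinkage))
      purrr::map_dfr(config$glm$analyses, function(a) {
        stage_try("glm", sprintf("subject %d / %s", s, a),
                  run_glm_suite(ser, set, analysis = a, covariates = covs,
                                residualize_predictors =
                                  config$glm$residualize_predictors)) |>
          dplyr::mutate(subject = s, .before = 1)
      })
    })
    eeg_stats <- eeg_betas |>
      dplyr::group_by(.data$analysis, .data$predictor) |>
      dplyr::group_modify(function(d, key) {
        sm <- stage_try(
          "stats", sprintf("%s / %s", key$analysis, key$predictor),
          sign_permutation_test(
            dplyr::select(d, "subject", time = "unit", beta = "beta"),
            n_iterations = config$stats$n_iterations,
            threshold_z = config$stats$threshold_z,
            seed = config$stats$seed))
        tidy(sm)
      }) |>
      dplyr::ungroup()
    bundle$eeg <- list(study = eeg, betas = eeg_betas, stats = eeg_stats)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(set), file.path(out_dir, "design.csv"),
                     row.names = FALSE)
    if (!is.null(bundle$fmri)) {
      utils::write.csv(as.data.frame(bundle$fmri$betas),
                       file.path(out_dir, "fmri_betas.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(bundle$fmri$stats),
                       file.path(out_dir, "fmri_stats.csv"),
                       row.names = FALSE)
    }
    if (!is.null(bundle$eeg)) {
      utils::write.csv(as.data.frame(bundle$eeg$betas),
                       file.path(out_dir, "eeg_betas.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(bundle$eeg$stats),
                       file.path(out_dir, "eeg_stats.csv"),
                       row.names = FALSE)
    }
    # no timestamp: outputs must be reconstructible (bit-identical) from
    # config + seeds alone
    prov <- list(
      config = config,
      package_version = as.character(utils::packageVersion("scenersa")),
      r_version = R.version.string
    )
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(bundle)
}

#' Subset an fMRI study by runs
#'
#' Supports split-half replication analyses (e.g. first vs second half of
#' the experiment).
#'
#' @param study An `fmri_study`.
#' @param runs Run indices to keep.
#' @return The subset `fmri_study`.
#' @export
subset_runs <- function(study, runs) {
  stopifnot(inherits(study, "fmri_study"))
  if (length(runs) == 0) stop("empty run selection", call. = FALSE)
  n_runs <- dim(study$subjects[[1]])[2]
  if (any(runs < 1 | runs > n_runs)) {
    stop("run selector out of range", call. = FALSE)
  }
  study$subjects <- lapply(study$subjects,
                           function(a) a[, runs, , drop = FALSE])
  study$n_runs <- length(runs)
  study
}

#' Subset an EEG study by trials
#'
#' @param study An `eeg_study` (or single `eeg_dataset`).
#' @param trials Trial indices to keep (applied per subject).
#' @return The subset study.
#' @export
subset_trials <- function(study, trials) {
  if (length(trials) == 0) stop("empty trial selection", call. = FALSE)
  take <- function(ds) {
    if (any(trials < 1 | trials > dim(ds$epochs)[1])) {
      stop("trial selector out of range", call. = FALSE)
    }
    ds$epochs <- ds$epochs[trials, , , drop = FALSE]
    ds$labels <- ds$labels[trials]
    ds
  }
  if (inherits(study, "eeg_dataset")) return(take(study))
  stopifnot(inherits(study, "eeg_study"))
  study$subjects <- lapply(study$subjects, take)
  study
}

#' Subset a study (and its stimulus set) by conditions
#'
#' Restricts an `fmri_study` or `eeg_study` to a subset of conditions,
#' reindexing them consecutively so downstream RDMs stay aligned with the
#' subset design (e.g. pairwise comparisons along the vertical axis:
#' `set$condition[set$vertical %in% c(1, 2)]`).
#'
#' @param study An `fmri_study` or `eeg_study`.
#' @param conditions Condition indices (canonical order) to keep.
#' @return The subset study; its `set` has `condition` renumbered 1..k.
#' @export
subset_conditions <- function(study, conditions) {
  conditions <- sort(unique(conditions))
  if (length(conditions) < 2) {
    stop("need at least two conditions", call. = FALSE)
  }
  if (any(!conditions %in% study$set$condition)) {
    stop("condition selector out of range", call. = FALSE)
  }
  new_set <- study$set[match(conditions, study$set$condition), , drop = FALSE]
  new_set$condition <- seq_len(nrow(new_set))
  if (inherits(study, "fmri_study")) {
    study$subjects <- lapply(study$subjects,
                             function(a) a[conditions, , , drop = FALSE])
  } else if (inherits(study, "eeg_study")) {
    study$subjects <- lapply(study$subjects, function(ds) {
      keep <- ds$labels %in% conditions
      ds$epochs <- ds$epochs[keep, , , drop = FALSE]
      ds$labels <- match(ds$labels[keep], conditions)
      ds
    })
  } else {
    stop("expected an fmri_study or eeg_study", call. = FALSE)
  }
  study$set <- new_set
  study
}
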