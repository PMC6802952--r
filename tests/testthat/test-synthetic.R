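test_that("generators are bit-reproducible given a seed and leave the RNG alone", {
  set <- tiny_set()
  a <- simulate_fmri(set, n_subjects = 2, n_voxels = 10, n_runs = 2, seed = 7)
  b <- simulate_fmri(set, n_subjects = 2, n_voxels = 10, n_runs = 2, seed = 7)
  expect_identical(a$subjects, b$subjects)
  c <- simulate_fmri(set, n_subjects = 2, n_voxels = 10, n_runs = 2, seed = 8)
  expect_false(identical(a$subjects, c$subjects))

  e1 <- simulate_eeg(set, n_subjects = 2, n_channels = 4, n_reps = 3,
                     times = seq(-100, 200, 20), seed = 5)
  e2 <- simulate_eeg(set, n_subjects = 2, n_channels = 4, n_reps = 3,
                     times = seq(-100, 200, 20), seed = 5)
  expect_identical(e1$subjects, e2$subjects)

  f1 <- simulate_features(set, n_layers = 3, layer_sizes = 20, seed = 3)
  f2 <- simulate_features(set, n_layers = 3, layer_sizes = 20, seed = 3)
  expect_identical(f1$layers, f2$layers)

  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_fmri(set, 1, 5, 2, seed = 1))
  expect_identical(rnorm(1), before) # caller's RNG stream undisturbed
})

test_that("generator design constraints are enforced", {
  set <- tiny_set()
  expect_error(simulate_fmri(set, 1, 10, n_runs = 1, seed = 1),
               "design error")
  expect_error(simulate_eeg(set, 1, 4, n_reps = 1, seed = 1), "design error")
  expect_error(simulate_eeg(set, 1, 4, n_reps = 3,
                            times = seq(0, 100, 20), seed = 1),
               "pre-stimulus")
  expect_error(simulate_features(set, n_layers = 2, category_gradient = 2,
                                 seed = 1), "category_gradient")
  d <- dim(simulate_eeg(set, 1, 17, 2, seed = 1)$subjects[[1]]$epochs)
  expect_equal(d, c(12 * 2, 17, 201)) # default -200..800 ms at 200 Hz
})

test_that("zero planted effects give chance-level structure downstream", {
  set.seed(1)
  set <- tiny_set()
  null <- ground_truth(0, 0, 0, 0, noise_sd = 1)
  # cross-validated dissimilarities: mean over Monte-Carlo draws near 0
  vals <- replicate(200, {
    fm <- simulate_fmri(set, 1, n_voxels = 8, n_runs = 2, truth = null,
                        seed = sample.int(1e6, 1))
    mean(lower_vals(crossval_corr_rdm(fm$subjects[[1]])))
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-3)

  # pairwise decoding near 0.5, pre- and post-stimulus alike
  eeg <- simulate_eeg(set, 1, n_channels = 6, n_reps = 6,
                      times = seq(-100, 200, 50), truth = null, seed = 11)
  ser <- decode_series(eeg$subjects[[1]])
  accs <- apply(ser$values, 3, function(m) mean(m[lower.tri(m)]))
  expect_true(all(abs(accs - 0.5) < 0.06))
})

test_that("a planted vertical effect lowers same-vertical dissimilarity", {
  set.seed(2)
  set <- tiny_set()
  truth <- ground_truth(vertical = 1, horizontal = 0, category = 0,
                        unique = 0.3, noise_sd = 1.5)
  v <- build_location_rdm(set, "vertical")
  same_v <- lower_vals(v) == 0
  # Monte Carlo over >= 100 simulated datasets
  diffs <- replicate(100, {
    fm <- simulate_fmri(set, 1, n_voxels = 12, n_runs = 2, truth = truth,
                        seed = sample.int(1e6, 1))
    d <- lower_vals(crossval_corr_rdm(demean_by_run(fm$subjects[[1]])))
    mean(d[!same_v]) - mean(d[same_v])
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs) / (sd(diffs) / sqrt(length(diffs))), 5)
})

test_that("EEG effects follow the planted time course", {
  set <- tiny_set()
  truth <- ground_truth(vertical = 2, horizontal = 0, category = 0,
                        unique = 0.5, noise_sd = 0.7,
                        eeg_onset_ms = 100, eeg_peak_ms = 200)
  a <- effect_time_course(truth, c(-100, 0, 100, 150, 200, 500))
  expect_equal(a[1:3], c(0, 0, 0))
  expect_equal(a[4], 0.5)
  expect_equal(a[5], 1)
  expect_lt(a[6], 1)

  eeg <- simulate_eeg(set, n_subjects = 6, n_channels = 8, n_reps = 6,
                      times = seq(-100, 250, 25), truth = truth, seed = 21)
  betas <- purrr::imap_dfr(eeg$subjects, function(ds, s) {
    run_glm_suite(decode_series(ds), set, "full") |>
      dplyr::mutate(subject = s)
  })
  vert <- betas |>
    dplyr::filter(.data$predictor == "vertical") |>
    dplyr::group_by(.data$unit) |>
    dplyr::summarise(beta = mean(.data$beta))
  pre <- vert$beta[vert$unit <= 100]  # effect is zero through onset
  post <- vert$beta[vert$unit >= 175]
  expect_lt(max(abs(pre)), 0.25)
  expect_gt(min(post), 0.5)
})

test_that("feature banks grade category structure across layers", {
  set <- build_stimulus_set()
  cat_rdm <- build_category_rdm(set)
  bank <- simulate_features(set, n_layers = 18, layer_sizes = 60,
                            category_gradient = 1, seed = 9)
  expect_length(bank$layers, 18)
  rdms <- bank_rdms(bank)
  rho <- vapply(rdms, function(r) {
    suppressWarnings(cor(lower_vals(r), lower_vals(cat_rdm),
                         method = "spearman"))
  }, 0)
  # monotone-increasing correlation with the category RDM along layers
  expect_lt(abs(rho[1]), 0.2)           # first layer ~ independent
  expect_gt(cor(seq_along(rho), rho), 0.9)
  # noise-free final layer is rank-equivalent to the category RDM: every
  # same-scene pair strictly below every different-scene pair (the Spearman
  # coefficient itself is ceiling-limited by the binary RDM's ties)
  fin <- lower_vals(rdms[[18]])
  same <- lower_vals(cat_rdm) == 0
  expect_lt(max(fin[same]), 1e-10)
  expect_gt(min(fin[!same]), 0.1)
  expect_gt(rho[18], 0.55)

  flat <- simulate_features(set, n_layers = 4, layer_sizes = 50,
                            category_gradient = 0, seed = 10)
  rho0 <- vapply(bank_rdms(flat), function(r) {
    suppressWarnings(cor(lower_vals(r), lower_vals(cat_rdm)))
  }, 0)
  expect_true(all(abs(rho0) < 0.2))
})
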