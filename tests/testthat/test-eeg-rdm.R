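make_eeg <- function(epochs, labels, times, sfreq = NULL) {
  structure(list(epochs = epochs, labels = labels, times = times,
                 sfreq = sfreq %||% (1000 / diff(times)[1]),
                 channels = sprintf("Ch%02d", seq_len(dim(epochs)[2]))),
            class = "eeg_dataset")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("baseline correction and boxcar downsampling behave as defined", {
  times <- seq(-200, 795, by = 5) # 200 Hz
  ep <- array(rnorm(4 * 3 * length(times)), dim = c(4, 3, length(times)))
  # constant trial -> all-zero after baseline correction
  ep[1, 1, ] <- 3.3
  out <- preprocess_epochs(make_eeg(ep, rep(1:2, 2), times))
  expect_equal(out$epochs[1, 1, ], rep(0, length(times)))
  # per trial and channel: baseline mean is zero afterwards
  bl <- times <= 0
  expect_lt(max(abs(apply(out$epochs[, , bl], c(1, 2), mean))), 1e-12)
  # idempotence on already-corrected data
  again <- preprocess_epochs(out)
  expect_equal(again$epochs, out$epochs)

  # 1000 Hz -> 200 Hz gives a 5 ms step via block averaging
  t1k <- seq(-200, 799, by = 1)
  ep1k <- array(rnorm(2 * 2 * length(t1k)), dim = c(2, 2, length(t1k)))
  ds <- preprocess_epochs(make_eeg(ep1k, 1:2, t1k), target_rate = 200)
  expect_equal(diff(ds$times)[1], 5)
  expect_equal(ds$sfreq, 200)
  expect_equal(ds$epochs[1, 1, 1], mean(ep1k[1, 1, 1:5] -
                                          mean(ep1k[1, 1, t1k <= 0])))
  expect_error(preprocess_epochs(make_eeg(ep1k, 1:2, t1k),
                                 target_rate = 300),
               "non-integer decimation")
})

test_that("channel selection is name-based, ordered, and validated", {
  times <- seq(-100, 100, 10)
  ep <- array(rnorm(2 * 17 * length(times)), dim = c(2, 17, length(times)))
  ds <- make_eeg(ep, 1:2, times)
  ds$channels <- posterior_channels()
  sel <- select_channels(ds, c("Oz", "O1"))
  expect_equal(sel$channels, c("Oz", "O1"))
  expect_equal(sel$epochs[, 1, ], ep[, 3, ]) # Oz is third in the montage
  expect_equal(select_channels(ds, posterior_channels())$epochs, ep)
  expect_error(select_channels(ds, c("O1", "Cz9")), "Cz9")
  expect_error(select_channels(ds, character(0)), "empty")
  expect_length(posterior_channels(), 17)
})

test_that("pairwise LDA accuracy equals fold-by-fold manual enumeration", {
  set.seed(7)
  for (rep in 1:8) {
    n <- sample(3:5, 1); p <- sample(2:4, 1)
    X1 <- matrix(rnorm(n * p, mean = 0.8), n, p)
    X2 <- matrix(rnorm(n * p), n, p)
    sh <- sample(c(0.05, 0.2), 1)
    expect_equal(scenersa:::.lda_pair_loo(X1, X2, sh),
                 oracle_lda_accuracy(X1, X2, sh), tolerance = 1e-10)
  }
  # 3-trials-per-condition, 2-channel hand-built instance
  X1 <- rbind(c(1, 0), c(1.2, 0.1), c(0.9, -0.1))
  X2 <- rbind(c(-1, 0), c(-1.1, 0.2), c(-0.8, 0))
  expect_equal(scenersa:::.lda_pair_loo(X1, X2, 0.05),
               oracle_lda_accuracy(X1, X2, 0.05))
  expect_equal(oracle_lda_accuracy(X1, X2, 0.05), 1) # separable clusters
})

test_that("decoding RDMs are bounded, symmetric, deterministic, chance-calibrated", {
  set.seed(8)
  times <- seq(-50, 100, 50)
  n_cond <- 4; n_reps <- 5
  labels <- rep(seq_len(n_cond), each = n_reps)
  ep <- array(rnorm(length(labels) * 3 * length(times)),
              dim = c(length(labels), 3, length(times)))
  ds <- make_eeg(ep, labels, times)
  r1 <- pairwise_decode_rdm(ds, 100)
  r2 <- pairwise_decode_rdm(ds, 100)
  expect_identical(unclass(r1), unclass(r2)) # deterministic
  expect_true(all(lower_vals(r1) >= 0 & lower_vals(r1) <= 1))
  expect_equal(unclass(r1), t(unclass(r1)))

  # label-shuffled data decodes at chance over permutations
  accs <- replicate(30, {
    ds$labels <- sample(labels)
    mean(lower_vals(pairwise_decode_rdm(ds, 0)))
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.01)

  # well-separated clusters decode perfectly
  sep <- ep
  sep[labels == 1, , ] <- sep[labels == 1, , ] * 0.1 + 10
  expect_equal(pairwise_decode_rdm(make_eeg(sep, labels, times), 0)[1, 2], 1)

  expect_error(pairwise_decode_rdm(make_eeg(ep[labels != 1, , ][-1, , ],
                                            labels[labels != 1][-1], times),
                                   0), ">= 2 trials")
})

test_that("decode_series yields one RDM per sample and matches per-point calls", {
  set.seed(9)
  set <- build_stimulus_set(1, 2, 1) # 4 conditions
  eeg <- simulate_eeg(set, 1, n_channels = 4, n_reps = 3,
                      times = seq(-200, 800, 5), seed = 31)
  ds <- eeg$subjects[[1]]
  ser <- decode_series(ds)
  expect_equal(length(ser$times), 201) # -200..800 ms at 200 Hz, inclusive
  expect_equal(dim(ser$values), c(4, 4, 201))
  one <- pairwise_decode_rdm(ds, 400)
  expect_equal(ser$values[, , which(ser$times == 400)],
               unclass(one), ignore_attr = TRUE)
  # fold exhaustiveness: every trial tested once per pair
  # (3 + 3 trials -> accuracies are multiples of 1/6)
  accs <- lower_vals(series_frame(ser, 0))
  expect_true(all(abs(accs * 6 - round(accs * 6)) < 1e-9))
})
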