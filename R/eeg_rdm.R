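#' Baseline-correct and downsample epoched EEG data
#'
#' Subtracts, for every trial and channel separately, the mean over the
#' pre-stimulus baseline window, then (optionally) downsamples the time
#' axis by boxcar-averaging consecutive samples. 1000 Hz data downsampled
#' to 200 Hz yields a 5 ms resolution.
#'
#' @param data An `eeg_dataset` (see [simulate_eeg()]).
#' @param baseline Length-2 ms interval `c(from, to)` within the
#'   pre-stimulus span; samples with `from <= t <= to` form the baseline.
#' @param target_rate Target sampling rate in Hz, or `NULL` to keep the
#'   original rate. The original rate must be an integer multiple.
#' @return The preprocessed `eeg_dataset`.
#' @export
preprocess_epochs <- function(data, baseline = c(-Inf, 0),
                              target_rate = NULL) {
  stopifnot(inherits(data, "eeg_dataset"))
  bl <- which(data$times >= baseline[1] & data$times <= baseline[2] &
                data$times <= 0)
  if (length(bl) == 0) {
    stop("baseline window contains no pre-stimulus samples", call. = FALSE)
  }
  bl_mean <- apply(data$epochs[, , bl, drop = FALSE], c(1, 2), mean)
  data$epochs <- data$epochs - as.vector(bl_mean) # recycles over time
  if (!is.null(target_rate)) {
    factor <- data$sfreq / target_rate
    if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
      stop(sprintf(
        "non-integer decimation factor: %g Hz cannot be reduced to %g Hz",
        data$sfreq, target_rate), call. = FALSE)
    }
    factor <- as.integer(round(factor))
    if (factor > 1L) {
      n_time <- dim(data$epochs)[3]
      n_out <- n_time %/% factor
      blocks <- split(seq_len(n_out * factor),
                      rep(seq_len(n_out), each = factor))
      new_epochs <- array(0, dim = c(dim(data$epochs)[1:2], n_out))
      for (b in seq_len(n_out)) {
        new_epochs[, , b] <-
          apply(data$epochs[, , blocks[[b]], drop = FALSE], c(1, 2), mean)
      }
      data$epochs <- new_epochs
      data$times <- unname(vapply(blocks, function(ix) mean(data$times[ix]), 0))
      data$sfreq <- data$sfreq / factor
    }
  }
  data
}

#' Select a subset of channels by name
#'
#' @param data An `eeg_dataset`.
#' @param channels Character vector of channel names (e.g.
#'   [posterior_channels()]); output channel order follows this list.
#' @return The channel-subset `eeg_dataset`.
#' @export
select_channels <- function(data, channels) {
  stopifnot(inherits(data, "eeg_dataset"))
  if (length(channels) == 0) stop("empty channel selection", call. = FALSE)
  missing <- setdiff(channels, data$channels)
  if (length(missing) > 0) {
    stop(sprintf("unknown channel(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  ix <- match(channels, data$channels)
  data$epochs <- data$epochs[, ix, , drop = FALSE]
  data$channels <- channels
  data
}

#' Pairwise LDA decoding RDM at a single time point
#'
#' For every unordered condition pair, trains and tests a two-class
#' linear discriminant analysis classifier on the channel values at the
#' given time point, with leave-one-trial-out cross-validation: each fold
#' holds out one trial of each condition, trains on the rest, and tests
#' the held-out trials; every trial is tested exactly once and the
#' accuracies are averaged. The pooled within-class covariance is shrunk
#' toward the scaled identity (`shrinkage`, default 0.05) so that few
#' trials with many channels never yield a singular covariance. Decoding
#' accuracy (chance 0.5) is the dissimilarity.
#'
#' @param data An `eeg_dataset`.
#' @param time_ms Time point in ms (nearest sample is used).
#' @param shrinkage Covariance shrinkage coefficient in `[0, 1)`.
#' @param labels Optional condition labels for the RDM.
#' @return An [rdm()] with kind `"decoding_accuracy"`.
#' @export
pairwise_decode_rdm <- function(data, time_ms, shrinkage = 0.05,
                                labels = NULL) {
  stopifnot(inherits(data, "eeg_dataset"))
  ti <- which.min(abs(data$times - time_ms))
  n_cond <- max(data$labels)
  if (min(table(factor(data$labels, levels = seq_len(n_cond)))) < 2) {
    stop("every condition needs >= 2 trials for leave-one-trial-out",
         call. = FALSE)
  }
  acc <- .decode_all(data$epochs[, , ti, drop = FALSE],
                     as.integer(data$labels), n_cond, shrinkage)
  m <- matrix(0, n_cond, n_cond)
  m[lower.tri(m)] <- acc[, 1]
  m <- m + t(m)
  rdm(m, kind = "decoding_accuracy", labels = labels)
}

#' Time-resolved pairwise decoding RDM series
#'
#' Runs [pairwise_decode_rdm()] at every sample of the epoch, yielding
#' one decoding-accuracy RDM per time point. Deterministic: no randomness
#' enters the decoding.
#'
#' @inheritParams pairwise_decode_rdm
#' @return An `rdm_series`: list with `values` (condition x condition x
#'   time array, diagonal `NA`), `times` (ms) and `kind`.
#' @export
decode_series <- function(data, shrinkage = 0.05, labels = NULL) {
  stopifnot(inherits(data, "eeg_dataset"))
  n_cond <- max(data$labels)
  if (min(table(factor(data$labels, levels = seq_len(n_cond)))) < 2) {
    stop("every condition needs >= 2 trials for leave-one-trial-out",
         call. = FALSE)
  }
  acc <- .decode_all(data$epochs, as.integer(data$labels), n_cond, shrinkage)
  arr <- array(NA_real_, dim = c(n_cond, n_cond, length(data$times)))
  lt <- lower.tri(matrix(0, n_cond, n_cond))
  for (t in seq_along(data$times)) {
    m <- matrix(0, n_cond, n_cond)
    m[lt] <- acc[, t]
    m <- m + t(m)
    diag(m) <- NA_real_
    arr[, , t] <- m
  }
  if (!is.null(labels)) dimnames(arr) <- list(labels, labels, NULL)
  rdm_series(arr, data$times, kind = "decoding_accuracy")
}

#' Construct an RDM series
#'
#' @param values Condition x condition x time array of dissimilarities.
#' @param times Time axis in ms (uniform step).
#' @param kind Kind tag shared by all frames.
#' @return A list with class `rdm_series`.
#' @export
rdm_series <- function(values, times, kind = "custom") {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(times))
  if (length(times) > 1) {
    steps <- diff(times)
    if (max(abs(steps - steps[1])) > 1e-9) {
      stop("times must be uniformly spaced", call. = FALSE)
    }
  }
  structure(list(values = values, times = times, kind = kind),
            class = "rdm_series")
}

#' @export
print.rdm_series <- function(x, ...) {
  cat(sprintf("<rdm_series> kind=%s, %d conditions, %d time points (%g..%g ms)\n",
              x$kind, dim(x$values)[1], length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Extract one RDM frame from a series
#'
#' @param series An [rdm_series()].
#' @param time_ms Time point in ms (nearest sample).
#' @return An [rdm()].
#' @export
series_frame <- function(series, time_ms) {
  stopifnot(inherits(series, "rdm_series"))
  ti <- which.min(abs(series$times - time_ms))
  rdm(series$values[, , ti], kind = series$kind,
      labels = dimnames(series$values)[[1]])
}
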