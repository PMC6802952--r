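#' Extract trial-averaged condition patterns from a volume time series
#'
#' Assigns each trial the volume at the TR closest to its onset, shifted
#' by `tr_shift` TRs to account for the hemodynamic delay (default 3 TRs,
#' i.e. 6 s at a 2 s TR), then averages trials within condition and run.
#' Trials whose shifted volume falls beyond the end of the series are
#' dropped with a warning.
#'
#' @param volume_series Numeric matrix, time (volumes) x voxel.
#' @param onsets Data frame with columns `run`, `condition` (1-based
#'   condition index) and `onset_s` (seconds from series start).
#' @param tr_s TR duration in seconds.
#' @param tr_shift Number of TRs to shift (>= 0); sweepable 0-5 to map
#'   the temporal response profile.
#' @param n_conditions Number of conditions (defaults to
#'   `max(onsets$condition)`).
#' @return Array condition x run x voxel of trial-averaged patterns;
#'   condition-run cells without any retained trial are `NA`.
#' @export
extract_trial_patterns <- function(volume_series, onsets, tr_s = 2,
                                   tr_shift = 3,
                                   n_conditions = max(onsets$condition)) {
  stopifnot(is.matrix(volume_series))
  if (tr_shift < 0) stop("tr_shift must be >= 0", call. = FALSE)
  needed <- c("run", "condition", "onset_s")
  if (!all(needed %in% names(onsets))) {
    stop("`onsets` needs columns run, condition, onset_s", call. = FALSE)
  }
  n_t <- nrow(volume_series)
  idx <- round(onsets$onset_s / tr_s) + 1L + as.integer(tr_shift)
  keep <- idx >= 1L & idx <= n_t
  if (any(!keep)) {
    warning(sprintf("%d trial(s) dropped: shifted volume beyond series end",
                    sum(!keep)), call. = FALSE)
  }
  runs <- sort(unique(onsets$run))
  out <- array(NA_real_,
               dim = c(n_conditions, length(runs), ncol(volume_series)))
  for (r in seq_along(runs)) {
    for (c in seq_len(n_conditions)) {
      sel <- keep & onsets$run == runs[r] & onsets$condition == c
      if (any(sel)) {
        out[c, r, ] <- colMeans(volume_series[idx[sel], , drop = FALSE])
      }
    }
  }
  out
}

#' Remove per-run mean activation from condition patterns
#'
#' Subtracts, separately for each run and voxel, the mean activation
#' across conditions. Removes run-wise baseline shifts so that
#' between-run pattern correlations reflect condition structure only.
#'
#' @param patterns Array condition x run x voxel.
#' @return Array of the same shape with zero mean over conditions within
#'   every run and voxel.
#' @export
demean_by_run <- function(patterns) {
  stopifnot(length(dim(patterns)) == 3)
  for (r in seq_len(dim(patterns)[2])) {
    sl <- patterns[, r, , drop = FALSE]
    dim(sl) <- dim(patterns)[c(1, 3)]
    patterns[, r, ] <- sweep(sl, 2, colMeans(sl), `-`)
  }
  patterns
}

# Correlation matrix between rows of A and rows of B, with zero-variance
# rows yielding r = 0 (warned once) instead of NA.
safe_row_cor <- function(A, B) {
  r <- suppressWarnings(stats::cor(t(A), t(B)))
  if (anyNA(r)) {
    warning("zero-variance pattern: correlation set to 0", call. = FALSE)
    r[is.na(r)] <- 0
  }
  r
}

fisher_z <- function(r, clip = 1 - 1e-12) atanh(pmin(pmax(r, -clip), clip))

#' Split-half cross-validated correlation RDM
#'
#' Computes the pairwise neural dissimilarity of conditions as a
#' cross-validated correlation difference. For every unordered split of
#' the runs into two equal halves, patterns are averaged within each
#' half; for each condition pair (i, j) the within-condition correlations
#' (i with i, j with j, across halves) and between-condition correlations
#' (i with j in both directions) are computed, Fisher-transformed
#' (clipped to |r| <= 1 - 1e-12 so noise-free data stays finite), and the
#' dissimilarity is mean(within) - mean(between). Values are averaged
#' over all possible splits (10 for 6 runs; C(2n, n)/2 in general).
#' Above-zero values indicate discriminable conditions; pure noise gives
#' an expected value of 0, so entries may be negative.
#'
#' @param patterns Array condition x run x voxel (typically run-demeaned
#'   via [demean_by_run()]).
#' @param labels Optional condition labels.
#' @return An [rdm()] with kind `"crossval_corr_diff"`.
#' @export
crossval_corr_rdm <- function(patterns, labels = NULL) {
  stopifnot(length(dim(patterns)) == 3)
  n_runs <- dim(patterns)[2]
  if (n_runs %% 2 != 0 || n_runs < 2) {
    stop("crossval_corr_rdm requires an even number of runs >= 2",
         call. = FALSE)
  }
  n_cond <- dim(patterns)[1]
  half <- n_runs / 2
  splits <- utils::combn(n_runs, half)
  # keep each unordered partition once: halves containing run 1
  splits <- splits[, splits[1, ] == 1, drop = FALSE]
  acc <- matrix(0, n_cond, n_cond)
  for (k in seq_len(ncol(splits))) {
    h1 <- splits[, k]
    h2 <- setdiff(seq_len(n_runs), h1)
    run_slice <- function(r) {
      s <- patterns[, r, , drop = FALSE]
      dim(s) <- dim(patterns)[c(1, 3)]
      s
    }
    A <- Reduce(`+`, lapply(h1, run_slice)) / length(h1)
    B <- Reduce(`+`, lapply(h2, run_slice)) / length(h2)
    z <- fisher_z(safe_row_cor(A, B)) # z[i, j] = z(cor(A_i, B_j))
    w <- outer(diag(z), diag(z), `+`) / 2          # mean within
    b <- (z + t(z)) / 2                            # mean between
    acc <- acc + (w - b)
  }
  rdm(acc / ncol(splits), kind = "crossval_corr_diff", labels = labels)
}

#' Number of unordered equal split-half partitions of the runs
#'
#' @param n_runs Even run count.
#' @return `choose(n_runs, n_runs / 2) / 2`, e.g. 10 for 6 runs.
#' @export
n_run_splits <- function(n_runs) {
  if (n_runs %% 2 != 0) stop("n_runs must be even", call. = FALSE)
  choose(n_runs, n_runs / 2) / 2
}
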