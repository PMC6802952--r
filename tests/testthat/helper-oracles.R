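# Independent brute-force oracles. These deliberately re-derive each
# quantity with the most literal scalar-level computation available, so
# they share no code path with the package implementations they check.

fisher_oracle <- function(r, clip = 1 - 1e-12) {
  r <- max(min(r, clip), -clip)
  0.5 * log((1 + r) / (1 - r))
}

# Cross-validated correlation RDM by explicit enumeration of every
# ordered half-split (each unordered partition visited twice, which
# leaves the average unchanged) and scalar correlations per pair.
oracle_crossval_rdm <- function(patterns) {
  n_cond <- dim(patterns)[1]
  n_runs <- dim(patterns)[2]
  halves <- utils::combn(n_runs, n_runs / 2)
  out <- matrix(NA_real_, n_cond, n_cond)
  half_mean <- function(cond, runs) {
    v <- rep(0, dim(patterns)[3])
    for (r in runs) v <- v + patterns[cond, r, ]
    v / length(runs)
  }
  for (i in seq_len(n_cond)) {
    for (j in seq_len(n_cond)) {
      if (i == j) next
      vals <- numeric(ncol(halves))
      for (s in seq_len(ncol(halves))) {
        h1 <- halves[, s]
        h2 <- setdiff(seq_len(n_runs), h1)
        ai <- half_mean(i, h1); aj <- half_mean(j, h1)
        bi <- half_mean(i, h2); bj <- half_mean(j, h2)
        zw <- (fisher_oracle(stats::cor(ai, bi)) +
                 fisher_oracle(stats::cor(aj, bj))) / 2
        zb <- (fisher_oracle(stats::cor(ai, bj)) +
                 fisher_oracle(stats::cor(aj, bi))) / 2
        vals[s] <- zw - zb
      }
      out[i, j] <- mean(vals)
    }
  }
  out
}

# Pairwise LDA leave-one-trial-out accuracy by explicit fold loop,
# classifying by Mahalanobis distance to the class means (equivalent
# discriminant, independently coded). Fold k holds out trial k of each
# class, as in the implementation's paired scheme.
oracle_lda_accuracy <- function(X1, X2, shrinkage = 0.05) {
  p <- ncol(X1)
  K <- max(nrow(X1), nrow(X2))
  correct <- 0; total <- 0
  for (k in seq_len(K)) {
    T1 <- if (k <= nrow(X1)) X1[-k, , drop = FALSE] else X1
    T2 <- if (k <= nrow(X2)) X2[-k, , drop = FALSE] else X2
    m1 <- colMeans(T1); m2 <- colMeans(T2)
    pooled <- (crossprod(sweep(T1, 2, m1)) + crossprod(sweep(T2, 2, m2))) /
      max(nrow(T1) + nrow(T2) - 2, 1)
    S <- (1 - shrinkage) * pooled +
      (shrinkage * sum(diag(pooled)) / p + 1e-12) * diag(p)
    Sinv <- solve(S)
    maha <- function(x, m) as.numeric(t(x - m) %*% Sinv %*% (x - m))
    if (k <= nrow(X1)) {
      x <- X1[k, ]
      total <- total + 1
      if (maha(x, m1) < maha(x, m2)) correct <- correct + 1
    }
    if (k <= nrow(X2)) {
      x <- X2[k, ]
      total <- total + 1
      if (maha(x, m2) <= maha(x, m1)) correct <- correct + 1
    }
  }
  correct / total
}

# OLS betas from the normal equations.
oracle_ols <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Residuals of y after projecting onto covariates + intercept, via the
# normal equations.
oracle_residualize <- function(y, covs) {
  X <- cbind(1, covs)
  y - X %*% solve(t(X) %*% X, t(X) %*% y)
}

# 1-D TFCE by explicit threshold loop with neighbor-scanning extents.
oracle_tfce <- function(map, E = 0.5, H = 2, dh = NULL, n_steps = 100) {
  out <- rep(0, length(map))
  mx <- max(map)
  if (mx <= 0) return(out)
  step <- if (is.null(dh)) mx / n_steps else dh
  for (kk in seq_len(floor(mx / step + 1e-9))) {
    h <- kk * step
    supra <- map > h
    for (t in which(supra)) {
      left <- t
      while (left > 1 && supra[left - 1]) left <- left - 1
      right <- t
      while (right < length(map) && supra[right + 1]) right <- right + 1
      extent <- right - left + 1
      out[t] <- out[t] + extent^E * h^H * step
    }
  }
  out
}

# Small helpers shared by tests -------------------------------------------

tiny_set <- function() build_stimulus_set(1, 3, 2) # 12 conditions

lower_vals <- function(m) {
  m <- as.matrix(m)
  m[lower.tri(m)]
}

# Per-subject three-predictor betas for an fmri_study.
fmri_study_betas <- function(study, analysis = "full", covariates = NULL,
                             ...) {
  purrr::imap_dfr(study$subjects, function(arr, s) {
    nr <- crossval_corr_rdm(demean_by_run(arr))
    run_glm_suite(nr, study$set, analysis = analysis,
                  covariates = covariates, ...) |>
      dplyr::mutate(subject = s)
  })
}
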