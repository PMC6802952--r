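# Group-level inference: one-tailed t-tests (fMRI), TFCE +
# max-statistic sign-permutation correction (EEG), latency bootstrap.

# Accept a subject x unit matrix or a tidy tibble (subject, unit, beta).
as_beta_matrix <- function(x, value_col = "beta") {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) {
    cols <- names(x)
    unit_col <- intersect(c("unit", "time"), cols)[1]
    val <- intersect(c(value_col, "value"), cols)[1]
    if (!is.na(unit_col) && "subject" %in% cols && !is.na(val)) {
      wide <- tidyr::pivot_wider(x[, c("subject", unit_col, val)],
                                 names_from = dplyr::all_of(unit_col),
                                 values_from = dplyr::all_of(val))
      m <- as.matrix(wide[, -1, drop = FALSE])
      rownames(m) <- wide$subject
      return(m)
    }
  }
  stop("expected a subject x unit matrix or a (subject, unit, beta) tibble",
       call. = FALSE)
}

#' One-sample group t-tests per unit
#'
#' Tests the across-subject mean beta against zero at every unit (ROI or
#' time point), one-tailed by default (alternative: mean greater than
#' zero). Zero across-subject variance is flagged with a warning and
#' yields an infinite statistic (p = 0 for a positive mean, 1 for a
#' negative one, 0.5 for all-zero betas).
#'
#' @param betas Subject x unit numeric matrix, or a tidy tibble with
#'   columns `subject`, `unit` (or `time`) and `beta`.
#' @param tail `"greater"` (one-tailed, default) or `"two.sided"`.
#' @return A tibble with columns `unit`, `estimate` (mean beta),
#'   `statistic` (t), `df`, `p.value`.
#' @export
group_ttest <- function(betas, tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  B <- as_beta_matrix(betas)
  n <- nrow(B)
  if (n < 2) stop("group_ttest needs >= 2 subjects", call. = FALSE)
  m <- colMeans(B)
  s <- apply(B, 2, stats::sd)
  t <- rep(NA_real_, length(m))
  zero_var <- s == 0
  if (any(zero_var)) {
    warning("zero across-subject variance in some unit(s)", call. = FALSE)
    t[zero_var] <- sign(m[zero_var]) * Inf
    t[zero_var & m == 0] <- 0
  }
  t[!zero_var] <- m[!zero_var] / (s[!zero_var] / sqrt(n))
  df <- n - 1
  p <- if (tail == "greater") stats::pt(t, df, lower.tail = FALSE) else
    2 * stats::pt(abs(t), df, lower.tail = FALSE)
  tibble::tibble(
    unit = colnames(B) %||% seq_along(m),
    estimate = unname(m), statistic = unname(t), df = df,
    p.value = unname(p)
  )
}

#' Bonferroni adjustment across a family of tests
#'
#' `p_adj = min(1, m * p)`; the default family size is the number of
#' p-values supplied (e.g. the three regions of interest).
#'
#' @param p Numeric vector of p-values.
#' @param m Family size (>= `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be >= number of tests", call. = FALSE)
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' One-dimensional threshold-free cluster enhancement
#'
#' Enhances a statistic map over a uniform time grid:
#' `TFCE(t) = sum_h e(h, t)^E * h^H * dh`, where `e(h, t)` is the extent
#' (in samples) of the contiguous suprathreshold run containing `t` at
#' threshold `h`, summed over thresholds `h = dh, 2dh, ...` up to the map
#' maximum. Negative map values contribute nothing (one-tailed use).
#' Defaults `E = 0.5`, `H = 2` and `dh = max(map)/100` follow common
#' practice for cluster enhancement of t-maps.
#'
#' @param stat_map Numeric vector, one statistic per time point.
#' @param E Extent exponent.
#' @param H Height exponent.
#' @param dh Threshold step; `NULL` uses `max(stat_map) / n_steps`.
#' @param n_steps Number of integration steps when `dh` is `NULL`.
#' @return Numeric vector of enhanced values (all zero if the map has no
#'   positive entries).
#' @export
tfce_1d <- function(stat_map, E = 0.5, H = 2, dh = NULL, n_steps = 100) {
  if (!is.null(dh) && dh <= 0) stop("dh must be positive", call. = FALSE)
  m <- matrix(as.numeric(stat_map), nrow = 1)
  as.vector(.tfce_batch(m, E, H, if (is.null(dh)) -1 else dh, n_steps))
}

# Vectorized sign-flip t-maps: flips is n_iter x n_subj of +-1.
flip_tmaps <- function(flips, B) {
  n <- nrow(B)
  mean_perm <- (flips %*% B) / n
  M2 <- matrix(colMeans(B^2), nrow = nrow(flips), ncol = ncol(B),
               byrow = TRUE)
  varu <- (M2 - mean_perm^2) * n / (n - 1)
  varu[varu < 1e-300] <- 1e-300
  mean_perm / sqrt(varu / n)
}

#' Sign-permutation test with TFCE max-statistic correction
#'
#' Group-level inference on a subject x time matrix of beta weights.
#' The observed group t-map is TFCE-enhanced ([tfce_1d()]). A null
#' distribution is built by flipping the sign of each subject's whole
#' beta time course independently at random on every iteration,
#' recomputing the t-map, enhancing it, and recording its maximum
#' (max-statistic family-wise error control). Observed enhanced values
#' are converted to Z against that null (moment-based by default, with
#' an empirical-quantile option) and thresholded at `threshold_z`
#' (default 1.64, i.e. p < 0.05 one-tailed). The integration step `dh`
#' is fixed from the observed map and reused for all null maps.
#'
#' @param betas Subject x time matrix, or tidy tibble with columns
#'   `subject`, `time`, `beta`.
#' @param times Time axis in ms (defaults to matrix column names or the
#'   sample index).
#' @param n_iterations Number of sign-flip iterations (default 10000).
#' @param threshold_z Z threshold for significance (default 1.64).
#' @param seed Integer seed (results are reproducible given the seed).
#' @param E,H,n_steps TFCE parameters, see [tfce_1d()].
#' @param z_method `"moment"` (empirical mean/SD of the null maxima) or
#'   `"quantile"` (empirical tail probability mapped through the normal
#'   quantile function).
#' @return A `stat_map` object: tidy table of `time`, `t`, `tfce`, `z`,
#'   `significant`, plus onset (first significant sample), peak (argmax
#'   of the group t-map) and peak t. Use [generics::tidy()] /
#'   [generics::glance()].
#' @export
sign_permutation_test <- function(betas, times = NULL, n_iterations = 10000,
                                  threshold_z = 1.64, seed,
                                  E = 0.5, H = 2, n_steps = 100,
                                  z_method = c("moment", "quantile")) {
  z_method <- match.arg(z_method)
  B <- as_beta_matrix(betas)
  if (nrow(B) < 2) stop("need >= 2 subjects", call. = FALSE)
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (n_iterations * stats::pnorm(threshold_z, lower.tail = FALSE) < 10) {
    warning("n_iterations is small for the requested threshold; ",
            "null tail is poorly resolved", call. = FALSE)
  }
  if (is.null(times)) {
    times <- suppressWarnings(as.numeric(colnames(B) %||% character(0)))
    if (length(times) != ncol(B) || anyNA(times)) times <- seq_len(ncol(B))
  }
  n <- nrow(B)
  tt <- group_ttest(B)$statistic
  dh <- if (max(tt) > 0) max(tt) / n_steps else
    if (max(abs(tt)) > 0) max(abs(tt)) / n_steps else 1 / n_steps
  tfce_obs <- as.vector(.tfce_batch(matrix(tt, nrow = 1), E, H, dh, n_steps))
  null_max <- with_seed(seed, {
    flips <- matrix(sample(c(-1, 1), n_iterations * n, replace = TRUE),
                    nrow = n_iterations)
    nt <- flip_tmaps(flips, B)
    apply(.tfce_batch(nt, E, H, dh, n_steps), 1, max)
  })
  if (z_method == "moment") {
    s <- stats::sd(null_max)
    z <- if (s > 0) (tfce_obs - mean(null_max)) / s else
      ifelse(tfce_obs > mean(null_max), Inf, -Inf)
  } else {
    p_emp <- vapply(tfce_obs,
                    function(v) (1 + sum(null_max >= v)) / (n_iterations + 1),
                    0)
    z <- stats::qnorm(1 - p_emp)
  }
  sig <- z > threshold_z & tt > 0
  onset <- if (any(sig)) times[which(sig)[1]] else NA_real_
  peak <- times[which.max(tt)]
  out <- list(
    table = tibble::tibble(time = times, t = tt, tfce = tfce_obs, z = z,
                           significant = sig),
    onset_ms = onset, peak_ms = peak, peak_t = max(tt),
    n_subjects = n,
    params = list(n_iterations = n_iterations, threshold_z = threshold_z,
                  E = E, H = H, dh = dh, z_method = z_method, seed = seed)
  )
  class(out) <- "stat_map"
  out
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d time points, %d significant\n",
              nrow(x$table), sum(x$table$significant)))
  cat(sprintf("  onset %s ms, peak %g ms (t = %.2f, n = %d)\n",
              ifelse(is.na(x$onset_ms), "n/a", format(x$onset_ms)),
              x$peak_ms, x$peak_t, x$n_subjects))
  invisible(x)
}

#' @export
tidy.stat_map <- function(x, ...) x$table

#' @export
glance.stat_map <- function(x, ...) {
  tibble::tibble(onset_ms = x$onset_ms, peak_ms = x$peak_ms,
                 peak_t = x$peak_t, n_significant = sum(x$table$significant),
                 n_subjects = x$n_subjects,
                 n_iterations = x$params$n_iterations)
}

#' Time course plot of a corrected statistic map
#'
#' @param object A `stat_map`.
#' @param ... Unused.
#' @return A ggplot object: group t over time with significant samples
#'   marked.
#' @export
autoplot.stat_map <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$t)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                        colour = "red", size = 0.8) +
    ggplot2::labs(x = "time (ms)", y = "group t",
                  title = "corrected significance (red)") +
    ggplot2::theme_minimal()
}

#' Bootstrap distributions of onset and peak latency
#'
#' Resamples subjects with replacement, recomputes the corrected
#' significance time course ([sign_permutation_test()]) on every
#' bootstrap sample, and records the onset (first significant sample)
#' and peak (argmax of the group t-map) latencies. Draws with no
#' significant time point contribute an undefined onset, reported as a
#' rate.
#'
#' @param betas Subject x time matrix or tidy tibble.
#' @param times Time axis in ms.
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer seed.
#' @param n_iterations Sign-flip iterations per draw (reduced by default:
#'   each draw runs a full permutation test).
#' @param threshold_z Z threshold.
#' @param ... Passed to [sign_permutation_test()].
#' @return A `latency_boot` object: tibble of per-draw `onset_ms` /
#'   `peak_ms`, percentile CIs, and the undefined-onset rate.
#' @export
latency_bootstrap <- function(betas, times = NULL, n_boot = 100, seed,
                              n_iterations = 1000, threshold_z = 1.64, ...) {
  B <- as_beta_matrix(betas)
  if (nrow(B) < 2) stop("need >= 2 subjects", call. = FALSE)
  sub_seeds <- with_seed(seed, {
    list(draws = replicate(n_boot, sample.int(nrow(B), replace = TRUE),
                           simplify = FALSE),
         seeds = sample.int(.Machine$integer.max - 1, n_boot))
  })
  res <- purrr::map2_dfr(sub_seeds$draws, sub_seeds$seeds, function(ix, s) {
    sm <- suppressWarnings(
      sign_permutation_test(B[ix, , drop = FALSE], times = times,
                            n_iterations = n_iterations,
                            threshold_z = threshold_z, seed = s, ...))
    tibble::tibble(onset_ms = sm$onset_ms, peak_ms = sm$peak_ms)
  })
  defined <- !is.na(res$onset_ms)
  out <- list(
    draws = res,
    onset_ci = if (any(defined))
      stats::quantile(res$onset_ms[defined], c(0.025, 0.975)) else
        c(`2.5%` = NA_real_, `97.5%` = NA_real_),
    peak_ci = stats::quantile(res$peak_ms, c(0.025, 0.975)),
    undefined_onset_rate = mean(!defined),
    n_boot = n_boot
  )
  class(out) <- "latency_boot"
  out
}

#' @export
print.latency_boot <- function(x, ...) {
  cat(sprintf("<latency_boot> %d draws; onset CI [%s, %s] ms; peak CI [%g, %g] ms\n",
              x$n_boot, format(x$onset_ci[1]), format(x$onset_ci[2]),
              x$peak_ci[1], x$peak_ci[2]))
  cat(sprintf("  undefined-onset rate: %.2f\n", x$undefined_onset_rate))
  invisible(x)
}

#' @export
tidy.latency_boot <- function(x, ...) x$draws

#' @export
glance.latency_boot <- function(x, ...) {
  tibble::tibble(onset_lo = x$onset_ci[1], onset_hi = x$onset_ci[2],
                 peak_lo = x$peak_ci[1], peak_hi = x$peak_ci[2],
                 undefined_onset_rate = x$undefined_onset_rate,
                 n_boot = x$n_boot)
}
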