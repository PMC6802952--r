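#' Vectorize an RDM into its canonical pair vector
#'
#' Extracts the lower off-diagonal entries in the package's canonical
#' pair order — the column-major lower triangle of the canonical
#' condition order (pair (i, j) with i > j, ordered by j then i) — and
#' discards everything else, including the diagonal. With a pair mask,
#' masked-out pairs are dropped.
#'
#' @param x An [rdm()] (or plain square symmetric matrix), or a
#'   `pair_mask`.
#' @param mask Optional `pair_mask` from [build_cross_type_mask()];
#'   only pairs with `TRUE` are retained.
#' @return A tibble with columns `i`, `j` (condition indices, `i > j`)
#'   and `value`, one row per retained unordered pair (630 for the
#'   default 36-condition design; 324 under the cross-type mask).
#' @export
rdm_vectorize <- function(x, mask = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n != ncol(x)) stop("RDM must be square", call. = FALSE)
  lt <- lower.tri(x)
  ij <- which(lt, arr.ind = TRUE)
  keep <- rep(TRUE, nrow(ij))
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(x))) {
      stop("mask size does not match the RDM", call. = FALSE)
    }
    keep <- mask[lt]
  }
  tibble::tibble(i = ij[keep, 1], j = ij[keep, 2],
                 value = x[lt][keep])
}

# Pull a plain value vector out of an rdm / vector-tibble / numeric input.
as_pair_vector <- function(x, mask = NULL) {
  if (is.matrix(x) || inherits(x, "rdm")) {
    rdm_vectorize(x, mask)$value
  } else if (is.data.frame(x) && "value" %in% names(x)) {
    x$value
  } else if (is.numeric(x)) {
    as.numeric(x)
  } else {
    stop("expected an rdm, a pair-vector tibble, or a numeric vector",
         call. = FALSE)
  }
}

# OLS via QR with rank check; returns list(coef, resid, fitted, r2).
ols_fit <- function(X, y, term_names) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- term_names[qrx$pivot[seq.int(qrx$rank + 1, ncol(X))]]
    stop(sprintf("rank-deficient design: predictor(s) %s are collinear",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  coef <- qr.coef(qrx, y)
  resid <- qr.resid(qrx, y)
  fitted <- y - resid
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(resid^2) / tss else NA_real_
  list(coef = coef, resid = resid, fitted = fitted, r2 = r2)
}

#' Fit a predictor-RDM regression (RDM GLM)
#'
#' Models a vectorized neural RDM as a linear combination of predictor
#' RDMs via ordinary least squares with an intercept. The criterion is
#' z-scored by default (predictors enter in raw form), so betas are on a
#' common scale across subjects and units; z-scoring rescales all betas
#' by a common positive factor and changes no sign or t-statistic. With
#' a pair mask, criterion and predictors alike are restricted to the
#' retained pairs and the z-scoring uses only those entries.
#'
#' @param criterion Neural [rdm()], pair-vector tibble from
#'   [rdm_vectorize()], or numeric vector.
#' @param predictors Named list of predictor RDMs / pair vectors.
#' @param mask Optional `pair_mask`, applied to criterion and predictors.
#' @param zscore_criterion Z-score the criterion before fitting
#'   (default `TRUE`).
#' @return An object of class `rdm_glm` with fields `betas` (named,
#'   excluding the intercept), `intercept`, `r_squared`, `n_pairs`,
#'   `residuals`. Use [generics::tidy()] / [generics::glance()].
#' @export
#' @examples
#' set <- build_stimulus_set()
#' preds <- list(vertical = build_location_rdm(set, "vertical"),
#'               horizontal = build_location_rdm(set, "horizontal"),
#'               category = build_category_rdm(set))
#' y <- 2 * as.matrix(preds$vertical) + as.matrix(preds$category)
#' diag(y) <- NA
#' fit <- rdm_glm(rdm(y), preds)
#' tidy(fit)
rdm_glm <- function(criterion, predictors, mask = NULL,
                    zscore_criterion = TRUE) {
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    stop("`predictors` must be a fully named list", call. = FALSE)
  }
  y <- as_pair_vector(criterion, mask)
  P <- vapply(predictors, as_pair_vector, numeric(length(y)), mask = mask)
  P <- matrix(P, nrow = length(y),
              dimnames = list(NULL, names(predictors)))
  degenerate <- FALSE
  if (zscore_criterion) {
    s <- stats::sd(y)
    if (s > 0) {
      y <- (y - mean(y)) / s
    } else {
      warning("zero-variance criterion: all betas set to 0", call. = FALSE)
      degenerate <- TRUE
    }
  } else if (stats::sd(y) == 0) {
    warning("zero-variance criterion: all betas set to 0", call. = FALSE)
    degenerate <- TRUE
  }
  if (degenerate) {
    betas <- stats::setNames(rep(0, ncol(P)), colnames(P))
    out <- list(betas = betas, intercept = mean(y), r_squared = NA_real_,
                n_pairs = length(y), residuals = rep(0, length(y)),
                zscored = zscore_criterion)
    class(out) <- "rdm_glm"
    return(out)
  }
  X <- cbind(`(intercept)` = 1, P)
  fit <- ols_fit(X, y, colnames(X))
  out <- list(betas = fit$coef[-1], intercept = unname(fit$coef[1]),
              r_squared = fit$r2, n_pairs = length(y),
              residuals = fit$resid, zscored = zscore_criterion)
  class(out) <- "rdm_glm"
  out
}

#' @export
print.rdm_glm <- function(x, ...) {
  cat(sprintf("<rdm_glm> %d pairs, R^2 = %.3f\n", x$n_pairs, x$r_squared))
  print(round(x$betas, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rdm_glm <- function(x, ...) {
  tibble::tibble(predictor = names(x$betas), beta = unname(x$betas))
}

#' @export
glance.rdm_glm <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n_pairs = x$n_pairs,
                 n_predictors = length(x$betas))
}

#' Residualize a neural RDM vector against covariate RDMs
#'
#' Returns the criterion minus its ordinary-least-squares projection onto
#' the covariates (plus intercept): the part of the neural dissimilarity
#' structure the covariate bank leaves unexplained. Used to remove
#' feature-model (e.g. network-layer) structure before re-estimating the
#' location and category predictors.
#'
#' @param criterion Neural [rdm()], pair-vector tibble, or numeric
#'   vector.
#' @param covariates List of covariate RDMs / pair vectors (one per
#'   available covariate RDM).
#' @param mask Optional `pair_mask` applied to criterion and covariates.
#' @return A tibble like [rdm_vectorize()]'s output whose `value` column
#'   holds the residuals (columns `i`, `j` present when the criterion was
#'   an RDM).
#' @export
rdm_residualize <- function(criterion, covariates, mask = NULL) {
  ij <- if (is.matrix(criterion) || inherits(criterion, "rdm")) {
    rdm_vectorize(criterion, mask)[c("i", "j")]
  } else if (is.data.frame(criterion) && all(c("i", "j") %in% names(criterion))) {
    criterion[c("i", "j")]
  } else {
    NULL
  }
  y <- as_pair_vector(criterion, mask)
  C <- vapply(covariates, as_pair_vector, numeric(length(y)), mask = mask)
  C <- matrix(C, nrow = length(y))
  X <- cbind(1, C)
  qrx <- qr(X)
  res <- qr.resid(qrx, y)
  if (is.null(ij)) {
    tibble::tibble(value = res)
  } else {
    tibble::tibble(ij, value = res)
  }
}

# Residualize the columns of Y (and optionally the predictor matrix P)
# on covariate matrix C, all over the same pair set.
project_out <- function(M, C) {
  qrx <- qr(cbind(1, C))
  qr.resid(qrx, M)
}

#' Run the four RDM-regression analyses over a neural RDM or RDM series
#'
#' Implements the package's analysis suite:
#' \describe{
#'   \item{`full`}{three-predictor GLM (vertical, horizontal, category).}
#'   \item{`dnn_resid`}{feature-covariate residualization followed by the
#'     three-predictor GLM.}
#'   \item{`cross_type`}{GLM restricted to cross-scene-type pairs, with
#'     vertical and horizontal predictors only (a category predictor
#'     cannot be constructed: all same-scene pairs are removed).}
#'   \item{`combined`}{residualization first, then the restricted
#'     cross-type GLM.}
#' }
#' In masked analyses the masked-out pairs are dropped from criterion and
#' predictors alike, and the criterion is z-scored over the retained
#' entries only.
#'
#' Residualized analyses are Frisch–Waugh consistent by default: the
#' criterion *and* the predictors of interest are residualized on the
#' covariate bank, which equals fitting one joint GLM with the covariates
#' as nuisance regressors. A predictor fully explained by the bank
#' (residual numerically zero) gets beta 0 with a warning rather than an
#' error. Set `residualize_predictors = FALSE` to residualize the
#' criterion only (the predictors then keep their covariate-correlated
#' part, which biases betas of predictors correlated with the bank).
#'
#' @param neural A neural [rdm()] or [rdm_series()].
#' @param set The stimulus set the RDM is aligned to.
#' @param analysis One of `"full"`, `"dnn_resid"`, `"cross_type"`,
#'   `"combined"`.
#' @param covariates List of covariate RDMs (required for residualized
#'   analyses), e.g. `bank_rdms(simulate_features(...))`.
#' @param predictors Optional named list of predictor RDMs overriding the
#'   defaults built from `set`. Requesting a `category` predictor in a
#'   cross-type analysis is an error.
#' @param residualize_predictors Logical; see Details.
#' @param zscore_criterion Z-score the criterion (default `TRUE`).
#' @return A tibble with columns `unit` (ROI label or time in ms),
#'   `predictor`, `beta`, `n_pairs`, `analysis`.
#' @export
run_glm_suite <- function(neural, set,
                          analysis = c("full", "dnn_resid", "cross_type",
                                       "combined"),
                          covariates = NULL, predictors = NULL,
                          residualize_predictors = TRUE,
                          zscore_criterion = TRUE) {
  analysis <- match.arg(analysis)
  assert_stimulus_set(set)
  restricted <- analysis %in% c("cross_type", "combined")
  residualized <- analysis %in% c("dnn_resid", "combined")
  if (residualized && (is.null(covariates) || length(covariates) == 0)) {
    stop("analysis '", analysis, "' needs a covariate bank", call. = FALSE)
  }
  if (is.null(predictors)) {
    predictors <- list(
      vertical = build_location_rdm(set, "vertical"),
      horizontal = build_location_rdm(set, "horizontal")
    )
    if (!restricted) {
      predictors$category <- build_category_rdm(set)
    }
  } else if (restricted && "category" %in% names(predictors)) {
    stop(paste("a category RDM cannot be constructed under the cross-type",
               "mask: all same-scene pairs are removed"), call. = FALSE)
  }
  mask <- if (restricted) build_cross_type_mask(set) else NULL
  mask_keep <- if (restricted) as.matrix(mask)[lower.tri(mask)] else NULL

  # criterion matrix: pairs x units, on the full pair set
  if (inherits(neural, "rdm_series")) {
    n_t <- length(neural$times)
    Y <- vapply(seq_len(n_t),
                function(t) as.matrix(neural$values[, , t])[
                  lower.tri(neural$values[, , t])],
                numeric(sum(lower.tri(neural$values[, , 1]))))
    Y <- matrix(Y, ncol = n_t)
    units <- neural$times
  } else {
    v <- as_pair_vector(neural)
    Y <- matrix(v, ncol = 1)
    units <- attr(neural, "unit") %||% "unit"
  }
  P_full <- vapply(predictors, as_pair_vector, numeric(nrow(Y)))
  P_full <- matrix(P_full, nrow = nrow(Y),
                   dimnames = list(NULL, names(predictors)))

  if (residualized) {
    # residualize on the full pair set, before any restriction
    Cm <- vapply(covariates, as_pair_vector, numeric(nrow(Y)))
    Cm <- matrix(Cm, nrow = nrow(Y))
    Y <- project_out(Y, Cm)
    if (residualize_predictors) {
      P_full <- project_out(P_full, Cm)
    }
  }
  if (restricted) {
    Y <- Y[mask_keep, , drop = FALSE]
    P_full <- P_full[mask_keep, , drop = FALSE]
  }

  # predictors annihilated by the covariate bank contribute beta 0
  sds <- apply(P_full, 2, stats::sd)
  dead <- sds < 1e-10
  if (any(dead)) {
    warning(sprintf(
      "predictor(s) %s fully explained by the covariate bank: beta set to 0",
      paste(colnames(P_full)[dead], collapse = ", ")), call. = FALSE)
  }
  X <- cbind(`(intercept)` = 1, P_full[, !dead, drop = FALSE])
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[seq.int(qrx$rank + 1, ncol(X))]]
    stop(sprintf("rank-deficient design: predictor(s) %s are collinear",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (zscore_criterion) {
    ysd <- apply(Y, 2, stats::sd)
    ok <- ysd > 0
    if (any(!ok)) {
      warning("zero-variance criterion in some unit(s): betas set to 0",
              call. = FALSE)
    }
    Y <- sweep(Y, 2, colMeans(Y), `-`)
    Y[, ok] <- sweep(Y[, ok, drop = FALSE], 2, ysd[ok], `/`)
    Y[, !ok] <- 0
  }
  coefs <- qr.coef(qrx, Y) # (1 + n_live) x units
  betas <- matrix(0, nrow = length(predictors), ncol = ncol(Y),
                  dimnames = list(names(predictors), NULL))
  betas[!dead, ] <- coefs[-1, , drop = FALSE]

  tidyr::expand_grid(unit = units, predictor = names(predictors)) |>
    dplyr::mutate(
      beta = as.vector(betas[cbind(match(.data$predictor, rownames(betas)),
                                   match(.data$unit, units))]),
      n_pairs = nrow(Y),
      analysis = analysis
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
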