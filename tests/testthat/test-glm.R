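test_that("vectorization keeps the canonical lower-triangle pair order", {
  set <- build_stimulus_set()
  v <- build_location_rdm(set, "vertical")
  vec <- rdm_vectorize(v)
  expect_equal(nrow(vec), 630) # C(36, 2)
  expect_true(all(vec$i > vec$j))
  # brute-force pair enumeration in the same order
  ij <- which(lower.tri(diag(36)), arr.ind = TRUE)
  expect_equal(vec$i, unname(ij[, 1]))
  expect_equal(vec$j, unname(ij[, 2]))
  expect_equal(vec$value, as.matrix(v)[lower.tri(v)])

  masked <- rdm_vectorize(v, build_cross_type_mask(set))
  expect_equal(nrow(masked), 324)
  # masked pairs all span scene types
  expect_true(all(set$scene_type[masked$i] != set$scene_type[masked$j]))

  two <- rdm(matrix(c(NA, 1, 1, NA), 2, 2))
  expect_equal(nrow(rdm_vectorize(two)), 1)
  expect_error(rdm_vectorize(v, mask = build_cross_type_mask(tiny_set())),
               "mask size")
})

test_that("rdm_glm matches the normal-equations oracle and recovers ratios", {
  set <- build_stimulus_set()
  preds <- list(vertical = build_location_rdm(set, "vertical"),
                horizontal = build_location_rdm(set, "horizontal"),
                category = build_category_rdm(set))
  # noise-free criterion 2*vertical + 1*category (then z-scored):
  # recovered ratio 2:1, horizontal exactly 0
  y <- 2 * as.matrix(preds$vertical) + as.matrix(preds$category)
  fit <- rdm_glm(rdm(y), preds)
  b <- fit$betas
  expect_equal(unname(b["vertical"] / b["category"]), 2, tolerance = 1e-10)
  expect_equal(unname(b["horizontal"]), 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # oracle equivalence on random instances, z-scoring on and off
  set.seed(13)
  for (rep in 1:5) {
    yv <- rnorm(630)
    for (zs in c(TRUE, FALSE)) {
      fit <- rdm_glm(yv, preds, zscore_criterion = zs)
      yy <- if (zs) as.numeric(scale(yv)) else yv
      X <- cbind(1, vapply(preds, lower_vals, numeric(630)))
      expect_equal(unname(fit$betas), oracle_ols(X, yy)[-1],
                   tolerance = 1e-10)
    }
  }

  # z-scoring rescales betas by one positive factor, flips no sign
  yv <- rnorm(630, sd = 4) + 2 * lower_vals(preds$vertical)
  f1 <- rdm_glm(yv, preds, zscore_criterion = TRUE)
  f2 <- rdm_glm(yv, preds, zscore_criterion = FALSE)
  expect_equal(unname(f1$betas / f2$betas),
               rep(1 / sd(yv), 3), tolerance = 1e-10)

  # criterion equal to one predictor: positive beta, zero residual variance
  fx <- rdm_glm(preds$vertical, preds)
  expect_gt(fx$betas["vertical"], 0)
  expect_lt(var(fx$residuals), 1e-20)

  # degenerate and invalid inputs
  expect_warning(f0 <- rdm_glm(rep(1, 630), preds), "zero-variance")
  expect_equal(unname(f0$betas), c(0, 0, 0))
  expect_error(rdm_glm(yv, c(preds, list(vertical2 = preds$vertical))),
               "collinear")
})

test_that("residualization is exact two-step OLS and annihilates its span", {
  set <- build_stimulus_set()
  cat_rdm <- build_category_rdm(set)
  vert <- build_location_rdm(set, "vertical")
  set.seed(14)
  yv <- rnorm(630) + 1.5 * lower_vals(cat_rdm)

  res <- rdm_residualize(yv, list(cat_rdm))
  expect_equal(res$value,
               as.numeric(oracle_residualize(yv, lower_vals(cat_rdm))),
               tolerance = 1e-10)
  # residuals orthogonal to the covariate and to the intercept
  expect_lt(abs(sum(res$value)), 1e-8)
  expect_lt(abs(sum(res$value * lower_vals(cat_rdm))), 1e-8)

  # orthogonal covariate: residuals = mean-centered criterion
  ortho <- rnorm(630)
  ortho <- ortho - mean(ortho)
  yc <- yv - mean(yv)
  ortho <- ortho - sum(ortho * yc) / sum(yc^2) * yc
  res2 <- rdm_residualize(yv, list(ortho))
  expect_equal(res2$value, yc, tolerance = 1e-8)

  # random small instance vs independent two-step OLS
  covs <- replicate(3, rnorm(630), simplify = FALSE)
  got <- rdm_residualize(yv, covs)$value
  want <- oracle_residualize(yv, do.call(cbind, covs))
  expect_equal(got, as.numeric(want), tolerance = 1e-10)
})

test_that("Frisch-Waugh consistency holds for the joint fit", {
  set <- build_stimulus_set()
  preds <- list(vertical = build_location_rdm(set, "vertical"),
                horizontal = build_location_rdm(set, "horizontal"),
                category = build_category_rdm(set))
  set.seed(15)
  yv <- rnorm(630) + lower_vals(preds$vertical)
  joint <- rdm_glm(yv, preds, zscore_criterion = FALSE)
  others <- preds[c("horizontal", "category")]
  y_res <- rdm_residualize(yv, others)$value
  p_res <- rdm_residualize(lower_vals(preds$vertical), others)$value
  beta_fwl <- sum(y_res * p_res) / sum(p_res^2)
  expect_equal(unname(joint$betas["vertical"]), beta_fwl, tolerance = 1e-10)
})

test_that("the GLM suite implements all four analyses coherently", {
  set <- build_stimulus_set()
  fm <- simulate_fmri(set, n_subjects = 6, n_voxels = 60, n_runs = 4,
                      truth = ground_truth(vertical = 0.8, horizontal = 0,
                                           category = 0.8, noise_sd = 2),
                      seed = 41)
  bank <- c(list(category = build_category_rdm(set)),
            bank_rdms(simulate_features(set, 4, 40, 0.9, seed = 42)))
  betas <- suppressWarnings(
    purrr::map_dfr(c("full", "dnn_resid", "cross_type", "combined"),
                   function(a) fmri_study_betas(fm, a, covariates = bank)))

  full <- dplyr::filter(betas, analysis == "full")
  expect_equal(sort(unique(full$predictor)),
               c("category", "horizontal", "vertical"))
  expect_equal(unique(full$n_pairs), 630)
  mean_full <- tapply(full$beta, full$predictor, mean)
  expect_gt(mean_full["vertical"], 0.1)
  expect_gt(mean_full["category"], 0.1)
  expect_lt(abs(mean_full["horizontal"]), 0.1)

  # restricted analysis: no category predictor, 324 cross-type pairs,
  # vertical survives with matching sign
  ct <- dplyr::filter(betas, analysis == "cross_type")
  expect_false("category" %in% ct$predictor)
  expect_equal(unique(ct$n_pairs), 324)
  expect_gt(mean(ct$beta[ct$predictor == "vertical"]), 0.1)

  # residualized analysis: category killed by a bank spanning it,
  # vertical preserved
  dr <- dplyr::filter(betas, analysis == "dnn_resid")
  expect_lt(abs(mean(dr$beta[dr$predictor == "category"])), 1e-10)
  expect_gt(mean(dr$beta[dr$predictor == "vertical"]), 0.1)

  cb <- dplyr::filter(betas, analysis == "combined")
  expect_equal(unique(cb$n_pairs), 324)
  expect_gt(mean(cb$beta[cb$predictor == "vertical"]), 0.05)

  # category under the cross-type mask is an explicit error
  expect_error(
    run_glm_suite(crossval_corr_rdm(fm$subjects[[1]]), set, "cross_type",
                  predictors = list(category = build_category_rdm(set))),
    "category RDM cannot be constructed")
  expect_error(run_glm_suite(crossval_corr_rdm(fm$subjects[[1]]), set,
                             "dnn_resid"), "covariate bank")
})
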