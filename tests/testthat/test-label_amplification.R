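make_amplification_data <- function() {
  fixture("amp_data", function() {
    co <- generate_cohort(200, seed = 10)
    list(
      cohort = co,
      metrics = generate_metrics(co, seed = 10),
      community = simulate_community_ratings(co, seed = 10),
      targets = aggregate_expert(simulate_expert_ratings(co, seed = 10))$binary
    )
  })
}

test_that("feature matrix modes produce the declared columns", {
  d <- make_amplification_data()
  fq <- build_feature_matrix(metrics = d$metrics, mode = "q")
  expect_equal(ncol(fq), 31L)
  expect_identical(colnames(fq), qc_metric_names())
  ff <- build_feature_matrix(community = d$community, mode = "f")
  n_raters <- length(unique(d$community$rater_id))
  expect_equal(ncol(ff), n_raters)
  fqf <- build_feature_matrix(metrics = d$metrics, community = d$community,
                              mode = "q+f")
  expect_equal(ncol(fqf), 31L + n_raters)
  expect_identical(unname(attr(fqf, "provenance")),
                   c(rep("metric", 31), rep("rater", n_raters)))
  expect_error(build_feature_matrix(mode = "q"), "requires the metrics")
  expect_error(build_feature_matrix(metrics = d$metrics, mode = "f"),
               "requires community")
})

test_that("an always-pass rater maps to an all-ones feature column", {
  co <- generate_cohort(30, seed = 11)
  cr <- simulate_community_ratings(
    co, n_raters = 2,
    rater_reliability = data.frame(sensitivity = c(1, 0.8),
                                   specificity = c(0, 0.8)),
    optimism = 0, coverage = 1, seed = 11
  )
  ff <- build_feature_matrix(community = cr, mode = "f")
  expect_true(all(ff[, 1] == 1))
})

test_that("calibration builds the configured number of weighted members", {
  d <- make_amplification_data()
  fq <- build_feature_matrix(metrics = d$metrics, mode = "q")
  ens <- fit_calibration(fq, d$targets, search_budget = 3, seed = 1)
  expect_s3_class(ens, "calibration_ensemble")
  expect_length(ens$members, 6L)  # 3 splits x 2 repeats
  expect_true(all(ens$weights >= 0 & ens$weights <= 1))
  # reported fold AUCs match an independent recomputation from stored
  # out-of-fold predictions
  recomputed <- vapply(split(ens$oof, list(ens$oof$repeat_i, ens$oof$fold)),
                       function(df) roc_auc(df$truth, df$pred), numeric(1))
  expect_equal(sort(unname(recomputed)), sort(ens$fold_auc))
  expect_equal(unname(ens$cv_auc["mean"]), mean(ens$fold_auc))
  expect_error(fit_calibration(fq, rep(1, nrow(fq))), "2 examples per class")
  expect_error(fit_calibration(fq[1:8, ], c(1, 0, 1, 0, rep(1, 4)),
                               n_splits = 3),
               "stratification")
})

test_that("perfectly separable features give near-unit weights", {
  set.seed(12)
  x <- cbind(sep = c(rnorm(40, -4), rnorm(40, 4)), noise = rnorm(80))
  y <- rep(c(0, 1), each = 40)
  ens <- fit_calibration(x, y, search_budget = 2, seed = 2)
  expect_true(all(ens$weights > 0.9))
  expect_gt(ens$cv_auc["mean"], 0.95)
})

test_that("ensemble prediction is the weight-normalized member average", {
  d <- make_amplification_data()
  fq <- build_feature_matrix(metrics = d$metrics, mode = "q")
  ens <- fit_calibration(fq, d$targets, search_budget = 2, seed = 3)
  p <- ensemble_predict(ens, fq)
  expect_true(all(p >= 0 & p <= 1))
  # single member: prediction equals that member's probability
  solo <- ens
  solo$members <- ens$members[1]
  solo$weights <- ens$weights[1]
  p1 <- predict(ens$members[[1]], xgboost::xgb.DMatrix(unclass(fq)))
  expect_equal(unname(ensemble_predict(solo, fq)), p1)
  # equal weights: plain mean of member probabilities
  eq <- ens
  eq$weights <- rep(0.5, length(ens$weights))
  pm <- vapply(ens$members,
               function(m) predict(m, xgboost::xgb.DMatrix(unclass(fq))),
               numeric(nrow(fq)))
  expect_equal(unname(ensemble_predict(eq, fq)), rowMeans(pm))
  # hand arithmetic: p = (0.9*0.2 + 0.6*0.8) / 1.5
  expect_equal((0.9 * 0.2 + 0.6 * 0.8) / 1.5, 0.44)
  # schema mismatch is rejected with the offending columns named
  bad <- fq[, -3]
  expect_error(ensemble_predict(ens, bad), qc_metric_names()[3])
})

test_that("ensemble prediction is monotone in any member probability", {
  # direct check on the voting formula with synthetic member outputs
  w <- c(0.9, 0.7, 0.8)
  p <- c(0.3, 0.6, 0.5)
  base <- sum(w * p) / sum(w)
  for (i in 1:3) {
    p2 <- p
    p2[i] <- p[i] + 0.2
    expect_gt(sum(w * p2) / sum(w), base)
  }
})

test_that("tree Shapley importance zeroes constant features", {
  d <- make_amplification_data()
  fq <- build_feature_matrix(metrics = d$metrics, mode = "q")
  ens <- fit_calibration(fq, d$targets, search_budget = 2, seed = 4)
  imp <- shapley_importance(ens, fq)
  expect_setequal(imp$feature, qc_metric_names())
  expect_true(all(diff(imp$mean_abs_shap) <= 1e-12))
  # acquisition descriptors are constant within this cohort's sites and are
  # never split on; informative metrics dominate
  const_cols <- c("raw_voxel_size_x", "t1_dimension_z", "t1_num_directions")
  expect_true(all(imp$mean_abs_shap[imp$feature %in% const_cols] < 1e-8))
  expect_gt(imp$mean_abs_shap[imp$feature == "raw_neighbor_corr"],
            max(imp$mean_abs_shap[imp$feature %in% const_cols]))
  expect_error(shapley_importance(42, fq), "fitted")
})

test_that("sampling Shapley agrees with exact enumeration and closed forms", {
  set.seed(13)
  d <- 4
  bg <- matrix(rnorm(20 * d), 20, d, dimnames = list(NULL, paste0("f", 1:d)))
  x <- matrix(rnorm(2 * d), 2, d, dimnames = list(NULL, paste0("f", 1:d)))
  f <- function(m) m[, 1] * 2 + m[, 2] * m[, 3] - exp(m[, 4] / 3)
  sh <- shapley_sampling(f, x, background = bg, n_samples = 200, seed = 1)
  for (i in 1:2) {
    exact <- oracle_shapley_exact(f, x[i, ], bg)
    expect_lt(max(abs(sh[i, ] - exact)), 0.05)
  }
  # additive model on independent features: phi_i = f_i(x_i) - mean f_i(bg_i),
  # recovered exactly at any permutation count
  g <- function(m) 3 * m[, 1] - 2 * m[, 2] + 0.5 * m[, 3] + m[, 4]
  shg <- shapley_sampling(g, x, background = bg, n_samples = 5, seed = 2)
  coefs <- c(3, -2, 0.5, 1)
  for (i in 1:2) {
    closed <- coefs * (x[i, ] - colMeans(bg))
    expect_equal(unname(shg[i, ]), unname(closed), tolerance = 1e-8)
  }
})

test_that("the learner downweights unreliable raters: losing the best rater hurts", {
  # four near-chance raters plus one near-oracle; dropping the oracle's
  # column must lower the community-only cross-validated AUC
  rel <- data.frame(sensitivity = c(rep(0.62, 4), 0.99),
                    specificity = c(rep(0.55, 4), 0.99))
  diffs <- vapply(1:3, function(s) {
    co <- generate_cohort(300, seed = s)
    y <- aggregate_expert(simulate_expert_ratings(co, seed = s + 50))$binary
    cr <- simulate_community_ratings(co, n_raters = 5,
                                     views_per_participant = 3,
                                     rater_reliability = rel, optimism = 0,
                                     coverage = 1, seed = s + 60)
    fmf <- build_feature_matrix(community = cr, mode = "f")
    full <- fit_calibration(fmf, y, search_budget = 3, seed = s)$cv_auc[["mean"]]
    drop <- fit_calibration(fmf[, -5], y, search_budget = 3,
                            seed = s)$cv_auc[["mean"]]
    full - drop
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(sum(diffs > 0), 2L)
})

test_that("ensembles survive serialization round trips", {
  d <- make_amplification_data()
  fq <- build_feature_matrix(metrics = d$metrics, mode = "q")
  ens <- fit_calibration(fq, d$targets, search_budget = 2, seed = 5)
  dir <- tempfile()
  save_calibration(ens, dir)
  ens2 <- load_calibration(dir)
  expect_equal(ensemble_predict(ens2, fq), ensemble_predict(ens, fq),
               tolerance = 1e-6)
  expect_equal(ens2$weights, ens$weights)
})
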