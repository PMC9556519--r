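#' Build the calibration feature matrix
#'
#' Assembles the features used to amplify gold-standard expert labels:
#' mode `"q"` uses the 31 automated data-quality metrics; mode `"f"` encodes
#' the community ratings as one column per rater holding that rater's mean
#' rating for the participant (`NA` where unrated), so that the downstream
#' learner can weight raters by their reliability; mode `"q+f"` concatenates
#' both.
#'
#' @param metrics metrics table from [generate_metrics()] (or an
#'   ImageQC-style data frame with `participant_id` and the 31 columns);
#'   required for modes `"q"` and `"q+f"`.
#' @param community long community ratings (`participant_id`, `rater_id`,
#'   `rating`); required for modes `"f"` and `"q+f"`.
#' @param mode one of `"q"`, `"f"`, `"q+f"`.
#' @param participants optional participant ids fixing the row set and
#'   order; defaults to the metrics table's ids (modes with `q`) or the
#'   rated participants (mode `"f"`).
#' @return numeric matrix with participant-id rownames; attributes `mode`
#'   and `provenance` (per-column `"metric"` or `"rater"`).
#' @export
build_feature_matrix <- function(metrics = NULL, community = NULL,
                                 mode = c("q", "f", "q+f"),
                                 participants = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("q", "q+f") && is.null(metrics)) {
    stop("mode ", mode, " requires the metrics table")
  }
  if (mode %in% c("f", "q+f") && is.null(community)) {
    stop("mode ", mode, " requires community ratings")
  }
  if (is.null(participants)) {
    participants <- if (!is.null(metrics)) {
      metrics$participant_id
    } else {
      sort(unique(community$participant_id))
    }
  }
  parts <- list()
  prov <- character(0)
  if (mode %in% c("q", "q+f")) {
    missing_cols <- setdiff(qc_metric_names(), names(metrics))
    if (length(missing_cols) > 0L) {
      stop("metrics table lacks columns: ", paste(missing_cols, collapse = ", "))
    }
    qm <- as.matrix(metrics[match(participants, metrics$participant_id),
                            qc_metric_names()])
    parts$q <- qm
    prov <- c(prov, rep("metric", ncol(qm)))
  }
  if (mode %in% c("f", "q+f")) {
    raters <- sort(unique(community$rater_id))
    fm <- matrix(NA_real_, length(participants), length(raters),
                 dimnames = list(NULL, raters))
    agg <- stats::aggregate(rating ~ participant_id + rater_id,
                            data = community, FUN = mean)
    ri <- match(agg$rater_id, raters)
    pi <- match(agg$participant_id, participants)
    keep <- !is.na(pi)
    fm[cbind(pi[keep], ri[keep])] <- agg$rating[keep]
    parts$f <- fm
    prov <- c(prov, rep("rater", ncol(fm)))
  }
  out <- do.call(cbind, parts)
  rownames(out) <- participants
  colnames(out) <- unlist(lapply(parts, colnames), use.names = FALSE)
  attr(out, "mode") <- mode
  attr(out, "provenance") <- stats::setNames(prov, colnames(out))
  class(out) <- c("qc_features", class(out))
  out
}

default_search_grid <- function() {
  list(
    max_depth = c(2L, 3L, 4L, 6L),
    eta = c(0.05, 0.1, 0.3),
    nrounds = c(50L, 100L, 200L),
    subsample = c(0.7, 1),
    colsample_bytree = c(0.6, 1)
  )
}

sample_config <- function(grid) {
  lapply(grid, function(v) v[[sample.int(length(v), 1)]])
}

fit_xgb_member <- function(x, y, cfg) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(
    params = list(
      objective = "binary:logistic",
      max_depth = cfg$max_depth, eta = cfg$eta,
      subsample = cfg$subsample, colsample_bytree = cfg$colsample_bytree,
      nthread = 1
    ),
    data = dtrain, nrounds = cfg$nrounds, verbose = 0
  )
}

stratified_folds <- function(y, n_splits) {
  if (min(table(y)) < n_splits) {
    stop("stratification error: a class has fewer examples than folds")
  }
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ix <- sample(which(y == cl))
    fold[ix] <- rep_len(seq_len(n_splits), length(ix))
  }
  fold
}

#' Fit the label-amplification calibration ensemble
#'
#' Trains one gradient-boosted tree binary classifier per cross-validation
#' fold of a repeated stratified K-fold scheme (defaults: 3 splits x 2
#' repeats = 6 members). In each fold, hyperparameters are chosen by
#' randomized search over a small grid, scored on a stratified inner
#' holdout of the training fold. Each member's voting weight is its ROC-AUC
#' on its held-out fold; out-of-fold predictions are retained so the
#' cross-validated performance (mean and sd over folds) can be recomputed.
#'
#' @param features a feature matrix from [build_feature_matrix()] (or any
#'   numeric matrix; `NA`s are handled natively by the tree learner).
#' @param targets binary labels (0/1) aligned to the rows, e.g. binarized
#'   scaled expert scores.
#' @param n_splits,n_repeats cross-validation scheme.
#' @param search_budget number of hyperparameter configurations drawn per
#'   fold.
#' @param grid named list of candidate hyperparameter values.
#' @param seed integer seed.
#' @return object of class `calibration_ensemble`: members, `weights`
#'   (out-of-sample AUCs), `fold_auc`, `cv_auc` (mean, sd), `oof`
#'   (out-of-fold prediction table) and the training configuration.
#' @export
fit_calibration <- function(features, targets, n_splits = 3L, n_repeats = 2L,
                            search_budget = 8L, grid = default_search_grid(),
                            seed = 1L) {
  x <- as.matrix(features)
  y <- as.numeric(targets)
  if (length(y) != nrow(x)) stop("targets must align with features")
  if (!all(y %in% c(0, 1))) stop("targets must be binary 0/1")
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("need >= 2 examples per class")
  }
  set.seed(seed)
  members <- list()
  weights <- numeric(0)
  fold_auc <- numeric(0)
  oof <- list()
  configs <- list()
  for (rep_i in seq_len(n_repeats)) {
    fold <- stratified_folds(y, n_splits)
    for (f in seq_len(n_splits)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      # inner stratified holdout for the hyperparameter search
      inner <- stratified_folds(y[tr], 4L)
      fit_ix <- tr[inner != 1L]
      val_ix <- tr[inner == 1L]
      best <- NULL
      best_auc <- -Inf
      for (s in seq_len(search_budget)) {
        cfg <- sample_config(grid)
        m <- fit_xgb_member(x[fit_ix, , drop = FALSE], y[fit_ix], cfg)
        p <- predict(m, xgboost::xgb.DMatrix(x[val_ix, , drop = FALSE]))
        a <- roc_auc(y[val_ix], p)
        if (a > best_auc) {
          best_auc <- a
          best <- cfg
        }
      }
      m <- fit_xgb_member(x[tr, , drop = FALSE], y[tr], best)
      p_te <- predict(m, xgboost::xgb.DMatrix(x[te, , drop = FALSE]))
      auc_te <- roc_auc(y[te], p_te)
      members[[length(members) + 1L]] <- m
      weights <- c(weights, auc_te)
      fold_auc <- c(fold_auc, auc_te)
      configs[[length(configs) + 1L]] <- best
      oof[[length(oof) + 1L]] <- data.frame(
        repeat_i = rep_i, fold = f, index = te, pred = p_te, truth = y[te]
      )
    }
  }
  structure(
    list(
      members = members, weights = weights, fold_auc = fold_auc,
      cv_auc = c(mean = mean(fold_auc), sd = stats::sd(fold_auc)),
      oof = do.call(rbind, oof),
      feature_names = colnames(x),
      mode = attr(features, "mode"),
      config = list(n_splits = n_splits, n_repeats = n_repeats,
                    search_budget = search_budget, seed = seed,
                    member_configs = configs)
    ),
    class = "calibration_ensemble"
  )
}

#' Amplified pass probability from the voting ensemble
#'
#' The ensemble prediction is the weighted average of the members' pass
#' probabilities, weighted by each member's out-of-sample ROC-AUC and
#' normalized by the weight sum.
#'
#' @param ensemble a `calibration_ensemble`.
#' @param features matrix with the training columns (order may differ;
#'   matched by name).
#' @return pass probabilities in \[0,1\], named by rowname.
#' @export
ensemble_predict <- function(ensemble, features) {
  stopifnot(inherits(ensemble, "calibration_ensemble"))
  x <- as.matrix(features)
  missing_cols <- setdiff(ensemble$feature_names, colnames(x))
  extra_cols <- setdiff(colnames(x), ensemble$feature_names)
  if (length(missing_cols) > 0L || length(extra_cols) > 0L) {
    stop("feature schema mismatch; missing: [",
         paste(missing_cols, collapse = ", "), "], unexpected: [",
         paste(extra_cols, collapse = ", "), "]")
  }
  x <- x[, ensemble$feature_names, drop = FALSE]
  dm <- xgboost::xgb.DMatrix(x)
  p <- vapply(ensemble$members, function(m) predict(m, dm),
              numeric(nrow(x)))
  if (nrow(x) == 1L) p <- matrix(p, nrow = 1L)
  out <- as.numeric(p %*% ensemble$weights / sum(ensemble$weights))
  names(out) <- rownames(x)
  out
}

#' Global feature importance via mean absolute Shapley values
#'
#' For tree ensembles, per-prediction Shapley values come from the
#' tree-path-dependent decomposition (`predcontrib`); member importances
#' are combined with the ensemble's voting weights. For an arbitrary model
#' supplied as a prediction function, a permutation-sampling estimator is
#' used (see [shapley_sampling()]).
#'
#' @param model a `calibration_ensemble`, or a function `f(X) -> numeric`
#'   (one prediction per row).
#' @param features the feature matrix to explain (as at training).
#' @param n_samples permutations per instance for the sampling estimator
#'   (ignored for tree models).
#' @param seed integer seed for the sampling estimator.
#' @return data frame (`feature`, `mean_abs_shap`) sorted descending.
#' @export
shapley_importance <- function(model, features, n_samples = 64L, seed = 1L) {
  x <- as.matrix(features)
  if (inherits(model, "calibration_ensemble")) {
    x <- x[, model$feature_names, drop = FALSE]
    dm <- xgboost::xgb.DMatrix(x)
    imp <- vapply(model$members, function(m) {
      contrib <- predict(m, dm, predcontrib = TRUE)
      cm <- colMeans(abs(contrib))
      cm[colnames(x)]
    }, numeric(ncol(x)))
    val <- as.numeric(imp %*% model$weights / sum(model$weights))
  } else if (is.function(model)) {
    sh <- shapley_sampling(model, x, n_samples = n_samples, seed = seed)
    val <- colMeans(abs(sh))
  } else {
    stop("model must be a fitted calibration_ensemble or a prediction function")
  }
  out <- data.frame(feature = colnames(x), mean_abs_shap = val,
                    stringsAsFactors = FALSE)
  out[order(-out$mean_abs_shap), , drop = FALSE]
}

#' Permutation-sampling Shapley values
#'
#' Monte-Carlo estimator of interventional Shapley values: for each sampled
#' feature permutation, features are switched from the background
#' distribution to the instance's values in permutation order, and each
#' feature is credited with the induced change in the model's
#' background-averaged output. Marginalization over the background is exact
#' (the full background set is evaluated at every step), so only the
#' permutation order is sampled; the estimate converges to the exact Shapley
#' value as `n_samples` grows, and is exact at any `n_samples` for additive
#' models.
#'
#' @param predict_fun function mapping a feature matrix to predictions.
#' @param x instances to explain (matrix).
#' @param background background data for the value function's expectation;
#'   defaults to `x`.
#' @param n_samples permutations per instance.
#' @param seed integer seed.
#' @return matrix instances x features of Shapley values.
#' @export
shapley_sampling <- function(predict_fun, x, background = x,
                             n_samples = 64L, seed = 1L) {
  set.seed(seed)
  x <- as.matrix(x)
  background <- as.matrix(background)
  d <- ncol(x)
  out <- matrix(0, nrow(x), d, dimnames = list(rownames(x), colnames(x)))
  for (i in seq_len(nrow(x))) {
    phi <- numeric(d)
    for (s in seq_len(n_samples)) {
      perm <- sample.int(d)
      z <- background
      prev <- mean(predict_fun(z))
      for (j in perm) {
        z[, j] <- x[i, j]
        cur <- mean(predict_fun(z))
        phi[j] <- phi[j] + (cur - prev)
        prev <- cur
      }
    }
    out[i, ] <- phi / n_samples
  }
  out
}

#' Serialize / restore a calibration ensemble
#'
#' Members are saved in the tree learner's native format; weights and the
#' training configuration go to a JSON sidecar.
#'
#' @param ensemble a `calibration_ensemble`.
#' @param path directory (created if absent).
#' @export
save_calibration <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "calibration_ensemble"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$members)) {
    xgboost::xgb.save(ensemble$members[[i]],
                      file.path(path, sprintf("member_%02d.ubj", i)))
  }
  meta <- list(weights = ensemble$weights, fold_auc = ensemble$fold_auc,
               cv_auc = as.list(ensemble$cv_auc),
               feature_names = ensemble$feature_names,
               mode = ensemble$mode,
               config = ensemble$config[c("n_splits", "n_repeats",
                                          "search_budget", "seed")])
  jsonlite::write_json(meta, file.path(path, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(ensemble$oof, file.path(path, "oof_predictions.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "ensemble.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(path, pattern = "^member_\\d+\\.ubj$",
                           full.names = TRUE))
  members <- lapply(files, xgboost::xgb.load)
  oof_path <- file.path(path, "oof_predictions.csv")
  structure(
    list(members = members, weights = meta$weights,
         fold_auc = meta$fold_auc,
         cv_auc = c(mean = meta$cv_auc$mean, sd = meta$cv_auc$sd),
         oof = if (file.exists(oof_path)) utils::read.csv(oof_path) else NULL,
         feature_names = meta$feature_names, mode = meta$mode,
         config = meta$config),
    class = "calibration_ensemble"
  )
}
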