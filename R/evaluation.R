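#' Area under the ROC curve
#'
#' Pairwise-concordance (Mann-Whitney) definition: the probability that a
#' randomly chosen positive outscores a randomly chosen negative, with ties
#' counted as half a concordance. Computed via the rank-sum identity.
#'
#' @param labels binary vector (0/1 or logical).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in \[0,1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores)) stop("labels/scores length mismatch")
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]; scores <- scores[keep]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC-AUC is undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Balanced accuracy
#'
#' The mean of sensitivity and specificity, robust to class imbalance.
#'
#' @param labels binary ground truth.
#' @param predictions binary predictions.
#' @return balanced accuracy in \[0,1\].
#' @export
balanced_accuracy <- function(labels, predictions) {
  labels <- as.numeric(labels); predictions <- as.numeric(predictions)
  if (length(unique(labels)) < 2L) {
    stop("balanced accuracy is undefined: both classes must be present")
  }
  sens <- mean(predictions[labels == 1] == 1)
  spec <- mean(predictions[labels == 0] == 0)
  (sens + spec) / 2
}

#' Leave-site-out generalization plan
#'
#' The default plan holds out each 3T site combination used in the study:
#' train CBIC+CUNY / eval RU; train CBIC / eval RU+CUNY; train RU+CUNY /
#' eval CBIC; train RU / eval CBIC+CUNY.
#'
#' @param model_family `"metrics-calibration"` (gradient-boosted ensemble on
#'   the automated metrics, trained on expert labels) or `"cnn"` (image-based
#'   network trained on amplified labels).
#' @param n_replicates replicate model fits per experiment; defaults follow
#'   the protocol (20 for the metrics family, 8 for the CNN family).
#' @param seeds integer seeds, one per replicate.
#' @return object of class `site_generalization_plan`.
#' @export
site_generalization_plan <- function(model_family = c("metrics-calibration",
                                                      "cnn"),
                                     n_replicates = NULL, seeds = NULL) {
  model_family <- match.arg(model_family)
  if (is.null(n_replicates)) {
    n_replicates <- if (model_family == "cnn") 8L else 20L
  }
  if (is.null(seeds)) seeds <- seq_len(n_replicates)
  experiments <- list(
    list(train_sites = c("CBIC", "CUNY"), eval_sites = "RU"),
    list(train_sites = "CBIC", eval_sites = c("RU", "CUNY")),
    list(train_sites = c("RU", "CUNY"), eval_sites = "CBIC"),
    list(train_sites = "RU", eval_sites = c("CBIC", "CUNY"))
  )
  for (e in experiments) {
    if (length(intersect(e$train_sites, e$eval_sites)) > 0L) {
      stop("train and eval sites must be disjoint")
    }
  }
  structure(list(model_family = model_family, experiments = experiments,
                 n_replicates = as.integer(n_replicates), seeds = seeds),
            class = "site_generalization_plan")
}

#' Run the leave-site-out generalization experiments
#'
#' For each experiment in the plan, replicate models are trained on the
#' training sites and scored on the held-out sites; accuracy, balanced
#' accuracy and ROC-AUC are reported as mean and standard deviation over
#' replicates.
#'
#' For the `"metrics-calibration"` family, `data` must contain `features`
#' (a metric feature matrix from [build_feature_matrix()]), binary `labels`
#' (expert pass/fail) and `site` per participant; each replicate is a
#' [fit_calibration()] ensemble with a different seed. For the `"cnn"`
#' family, `data` must additionally contain `volumes` and `targets`
#' (amplified QC scores); when `expert_labels` (with NAs outside the
#' gold-standard subset) are supplied, the held-out evaluation is decomposed
#' into a report set scored against expert labels and a test set scored
#' against the amplified labels.
#'
#' @param plan a [site_generalization_plan()].
#' @param data named list as described above.
#' @param ... tuning arguments forwarded to the family's fitting routine
#'   (e.g. `search_budget`, `max_epochs`).
#' @return data frame with one row per (experiment, evaluation set):
#'   columns `model`, `split`, `eval_set`, `n_eval`, and mean/sd of
#'   `accuracy`, `balanced_accuracy`, `roc_auc`.
#' @export
run_site_generalization <- function(plan, data, ...) {
  stopifnot(inherits(plan, "site_generalization_plan"))
  site <- as.character(data$site)
  need <- unique(unlist(lapply(plan$experiments,
                               function(e) c(e$train_sites, e$eval_sites))))
  missing_sites <- setdiff(need, unique(site))
  if (length(missing_sites) > 0L) {
    stop("sites not present in the data: ", paste(missing_sites, collapse = ", "))
  }
  rows <- list()
  for (ex in plan$experiments) {
    tr <- site %in% ex$train_sites
    ev <- site %in% ex$eval_sites
    split_lab <- sprintf("train: %s, test: %s",
                         paste(ex$train_sites, collapse = " + "),
                         paste(ex$eval_sites, collapse = " + "))
    if (plan$model_family == "metrics-calibration") {
      res <- replicate_metrics_family(plan$seeds, data, tr, ev, ...)
      rows[[length(rows) + 1L]] <- summarize_site_metrics(
        "XGB-q", split_lab, "expert", res, sum(ev)
      )
    } else {
      res <- replicate_cnn_family(plan$seeds, data, tr, ev, ...)
      for (set_name in names(res)) {
        rows[[length(rows) + 1L]] <- summarize_site_metrics(
          "CNN-i", split_lab, set_name, res[[set_name]],
          attr(res[[set_name]], "n_eval")
        )
      }
    }
  }
  do.call(rbind, rows)
}

replicate_metrics_family <- function(seeds, data, tr, ev, ...) {
  y_tr <- data$labels[tr]
  if (length(unique(data$labels[ev])) < 2L) {
    stop("held-out sites must contain both classes")
  }
  feats <- data$features
  lapply(seeds, function(s) {
    ens <- fit_calibration(feats[tr, , drop = FALSE], y_tr, seed = s, ...)
    p <- ensemble_predict(ens, feats[ev, , drop = FALSE])
    y <- data$labels[ev]
    c(accuracy = mean((p >= 0.5) == y),
      balanced_accuracy = balanced_accuracy(y, as.numeric(p >= 0.5)),
      roc_auc = roc_auc(y, p))
  })
}

replicate_cnn_family <- function(seeds, data, tr, ev, max_epochs = 10L, ...) {
  spec <- data$spec
  if (is.null(spec)) spec <- qc_network_spec()
  targets <- as.numeric(data$targets >= 0.5)
  vols <- data$volumes
  expert <- data$expert_labels
  test_idx <- which(ev & (if (is.null(expert)) TRUE else is.na(expert)))
  report_idx <- if (is.null(expert)) integer(0) else which(ev & !is.na(expert))
  score <- function(idx, truth) {
    function(models) {
      p <- predict_qc(models, vols[idx])
      y <- truth[idx]
      c(accuracy = mean((p >= 0.5) == y),
        balanced_accuracy = balanced_accuracy(y, as.numeric(p >= 0.5)),
        roc_auc = roc_auc(y, p))
    }
  }
  out <- list()
  per_rep <- lapply(seeds, function(s) {
    fit <- train_qc_cnn(build_qc_cnn(spec, seed = s), vols[which(tr)],
                        targets[tr], max_epochs = max_epochs, seed = s, ...)
    list(fit$model)
  })
  if (length(test_idx) > 0L) {
    out$test <- lapply(per_rep, score(test_idx, targets))
    attr(out$test, "n_eval") <- length(test_idx)
  }
  if (length(report_idx) > 0L) {
    out$report <- lapply(per_rep, score(report_idx, expert))
    attr(out$report, "n_eval") <- length(report_idx)
  }
  out
}

summarize_site_metrics <- function(model, split, eval_set, res, n_eval) {
  m <- do.call(rbind, res)
  data.frame(
    model = model, split = split, eval_set = eval_set, n_eval = n_eval,
    accuracy = mean(m[, "accuracy"]), accuracy_sd = stats::sd(m[, "accuracy"]),
    balanced_accuracy = mean(m[, "balanced_accuracy"]),
    balanced_accuracy_sd = stats::sd(m[, "balanced_accuracy"]),
    roc_auc = mean(m[, "roc_auc"]), roc_auc_sd = stats::sd(m[, "roc_auc"]),
    stringsAsFactors = FALSE
  )
}
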