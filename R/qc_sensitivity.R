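#' Pivot long bundle profiles to the participant x feature table
#'
#' One column per (bundle, metric, node) triple named
#' `<bundle>_<metric>_<node>`; a participant with all 24 bundles contributes
#' 4,800 features. Missing (participant, bundle) pairs yield `NA` blocks.
#'
#' @param profiles long data frame from [generate_bundle_profiles()] or a
#'   combined tract-profiles CSV read with [read_tract_profiles()].
#' @return numeric matrix with participant-id rownames and 4,800 columns in
#'   a fixed schema order.
#' @export
profiles_to_features <- function(profiles) {
  cols <- as.vector(outer(
    0:99,
    as.vector(outer(c("FA", "MD"), bundle_names(),
                    function(m, b) paste(b, m, sep = "_"))),
    function(n, bm) paste(bm, n, sep = "_")
  ))
  cols <- sort(cols)
  ids <- unique(profiles$participant_id)
  key <- paste(profiles$bundle, profiles$metric, profiles$node, sep = "_")
  out <- matrix(NA_real_, length(ids), length(cols),
                dimnames = list(ids, cols))
  ri <- match(profiles$participant_id, ids)
  ci <- match(key, cols)
  out[cbind(ri, ci)] <- profiles$value
  out
}

#' Median imputation of missing feature values
#'
#' Replaces each missing entry with the median of the observed values of
#' its feature; observed entries are untouched.
#'
#' @param features numeric matrix (participants x features).
#' @return complete matrix of the same shape.
#' @export
impute_median <- function(features) {
  x <- as.matrix(features)
  all_missing <- colSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    stop("features with no observed values: ",
         paste(utils::head(colnames(x)[all_missing], 5), collapse = ", "))
  }
  for (j in which(colSums(is.na(x)) > 0L)) {
    x[is.na(x[, j]), j] <- stats::median(x[, j], na.rm = TRUE)
  }
  x
}

#' Remove site (batch) effects from a feature table
#'
#' `"location-scale"` estimates each site's per-feature mean and standard
#' deviation directly and maps every site onto the pooled location and
#' scale. `"empirical-bayes"` uses the parametric ComBat estimator (via the
#' sva package), which shrinks the per-site effects across features and is
#' preferable when sites are small. Both preserve the grand-mean structure.
#'
#' @param features numeric matrix (participants x features), complete.
#' @param site site label per participant.
#' @param method `"location-scale"` or `"empirical-bayes"`.
#' @return harmonized matrix of the same shape.
#' @export
harmonize_sites <- function(features, site,
                            method = c("location-scale", "empirical-bayes")) {
  method <- match.arg(method)
  x <- as.matrix(features)
  site <- as.character(site)
  if (length(site) != nrow(x)) stop("site must align with rows")
  tab <- table(site)
  if (length(tab) < 2L) {
    message("single site: harmonization is the identity transform")
    return(x)
  }
  if (any(tab < 2L)) stop("need >= 2 participants per site")
  if (method == "empirical-bayes") {
    if (!requireNamespace("sva", quietly = TRUE)) {
      stop("the empirical-bayes method requires the sva package")
    }
    out <- t(sva::ComBat(dat = t(x), batch = site))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  gm <- colMeans(x)
  pooled_sd <- apply(x, 2L, stats::sd)
  pooled_sd[pooled_sd == 0] <- 1
  out <- x
  for (s in names(tab)) {
    ix <- which(site == s)
    sm <- colMeans(x[ix, , drop = FALSE])
    ssd <- apply(x[ix, , drop = FALSE], 2L, stats::sd)
    ssd[ssd == 0] <- 1
    out[ix, ] <- sweep(sweep(x[ix, , drop = FALSE], 2L, sm), 2L,
                       pooled_sd / ssd, `*`)
    out[ix, ] <- sweep(out[ix, , drop = FALSE], 2L, gm, `+`)
  }
  out
}

#' QC-cutoff sensitivity of cross-validated age prediction
#'
#' For every QC cutoff on the grid (default 0 to 0.95 in steps of 0.05),
#' participants with `qc_scores >= cutoff` are retained and a
#' gradient-boosted tree regressor is fit to the bundle-profile feature
#' table against log-transformed age under repeated K-fold cross-validation
#' (default 5 folds x 5 repeats). Predictions are back-transformed to years
#' before scoring, so R-squared is on the age scale.
#'
#' @param features complete participants x features matrix (impute and
#'   harmonize first; see [impute_median()], [harmonize_sites()]).
#' @param age age in years.
#' @param qc_scores QC scores in \[0,1\].
#' @param cutoffs cutoff grid.
#' @param n_folds,n_repeats cross-validation scheme.
#' @param xgb_params,nrounds regressor configuration (fixed defaults,
#'   recorded in the result's attributes).
#' @param seed integer seed.
#' @return data frame (`cutoff`, `mean_r2`, `sd_r2`, `ci_low`, `ci_high`,
#'   `n_retained`); cutoffs whose retained sample cannot sustain the fold
#'   scheme are reported with `NA` scores.
#' @export
age_prediction_sweep <- function(features, age, qc_scores,
                                 cutoffs = seq(0, 0.95, by = 0.05),
                                 n_folds = 5L, n_repeats = 5L,
                                 xgb_params = list(max_depth = 3, eta = 0.15,
                                                   subsample = 0.8,
                                                   colsample_bytree = 0.1,
                                                   tree_method = "exact"),
                                 nrounds = 40L, seed = 1L) {
  x <- as.matrix(features)
  stopifnot(length(age) == nrow(x), length(qc_scores) == nrow(x))
  if (anyNA(x)) stop("features must be complete; run impute_median() first")
  set.seed(seed)
  rows <- lapply(cutoffs, function(ct) {
    keep <- which(qc_scores >= ct)
    if (length(keep) < 2L * n_folds) {
      return(data.frame(cutoff = ct, mean_r2 = NA_real_, sd_r2 = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_retained = length(keep)))
    }
    xs <- x[keep, , drop = FALSE]
    ys <- log(age[keep])
    r2 <- numeric(0)
    for (r in seq_len(n_repeats)) {
      fold <- sample(rep_len(seq_len(n_folds), length(keep)))
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        if (stats::var(ys[!tr]) < 1e-12 || stats::var(ys[tr]) < 1e-12) {
          warning("degenerate age variance in a fold at cutoff ", ct)
          r2 <- c(r2, NA_real_)
          next
        }
        fit <- xgboost::xgb.train(
          params = c(list(objective = "reg:squarederror", nthread = 1),
                     xgb_params),
          data = xgboost::xgb.DMatrix(xs[tr, , drop = FALSE], label = ys[tr]),
          nrounds = nrounds, verbose = 0
        )
        pred <- exp(predict(fit, xgboost::xgb.DMatrix(xs[!tr, , drop = FALSE])))
        truth <- exp(ys[!tr])
        r2 <- c(r2, 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2))
      }
    }
    m <- mean(r2, na.rm = TRUE)
    s <- stats::sd(r2, na.rm = TRUE)
    half <- 1.96 * s / sqrt(sum(!is.na(r2)))
    data.frame(cutoff = ct, mean_r2 = m, sd_r2 = s,
               ci_low = m - half, ci_high = m + half,
               n_retained = length(keep))
  })
  out <- do.call(rbind, rows)
  attr(out, "regressor") <- c(xgb_params, list(nrounds = nrounds))
  attr(out, "cv") <- c(n_folds = n_folds, n_repeats = n_repeats)
  out
}

#' Read / write tract-profile tables
#'
#' Long CSV with columns `participant_id`, `bundle`, `metric`, `node`,
#' `value` (combined tract-profiles style).
#'
#' @param path CSV path.
#' @param profiles long profile data frame.
#' @export
read_tract_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "bundle", "metric", "node", "value")
  if (!all(need %in% names(df))) {
    stop("profile CSV must contain: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_tract_profiles
#' @export
write_tract_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}
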