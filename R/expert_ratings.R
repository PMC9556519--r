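#' Aggregate expert ratings to the released score scale
#'
#' Averages each participant's ratings over non-missing experts, rescales
#' the mean from \[-2, 2\] to \[0, 1\] via `(mean + 2) / 4`, binarizes at
#' 0.5, and assigns the ordinal category from the 0.2-width bands: a scaled
#' score in \[0, 0.2) is "definitely fail", \[0.2, 0.4) "probably fail",
#' \[0.4, 0.6) "not sure", \[0.6, 0.8) "probably pass" and \[0.8, 1\]
#' "definitely pass".
#'
#' @param ratings participants x experts matrix with entries in -2..2;
#'   missing ratings as `NA`. Rownames are participant ids.
#' @return data frame with `participant_id`, `mean_raw`, `scaled`, `binary`,
#'   `category`. Participants with no ratings yield explicit `NA` rows.
#' @export
aggregate_expert <- function(ratings) {
  ratings <- as.matrix(ratings)
  ok <- ratings[!is.na(ratings)]
  if (length(ok) && !all(ok %in% -2:2)) {
    stop("ratings must be on the 5-level scale -2..2")
  }
  n_rated <- rowSums(!is.na(ratings))
  mean_raw <- ifelse(n_rated > 0, rowMeans(ratings, na.rm = TRUE), NA_real_)
  scaled <- (mean_raw + 2) / 4
  cats <- c("definitely fail", "probably fail", "not sure",
            "probably pass", "definitely pass")
  category <- ifelse(is.na(scaled), NA_character_,
                     cats[findInterval(scaled, c(0.2, 0.4, 0.6, 0.8)) + 1L])
  data.frame(
    participant_id = if (is.null(rownames(ratings))) {
      as.character(seq_len(nrow(ratings)))
    } else rownames(ratings),
    mean_raw = mean_raw,
    scaled = scaled,
    binary = ifelse(is.na(scaled), NA_integer_, as.integer(scaled >= 0.5)),
    category = category,
    stringsAsFactors = FALSE
  )
}

#' Map a scaled \[0,1\] QC score onto the 5-level rating scale
#'
#' Inverse of the score rescaling used by [aggregate_expert()], for treating
#' continuous model scores as an ordinal coder (e.g. in a pairwise-kappa
#' matrix).
#'
#' @param scaled numeric scores in \[0,1\].
#' @return integer ratings in -2..2.
#' @export
score_to_rating <- function(scaled) {
  if (any(scaled < 0 | scaled > 1, na.rm = TRUE)) {
    stop("scaled scores must be in [0, 1]")
  }
  out <- findInterval(scaled, c(0.2, 0.4, 0.6, 0.8)) - 2L
  out[is.na(scaled)] <- NA_integer_
  out
}

#' Quadratic-weighted Cohen's kappa
#'
#' Chance-corrected ordinal agreement with squared-distance disagreement
#' weights: `kappa = 1 - sum(w * O) / sum(w * E)` with
#' `w[i,j] = (i - j)^2 / (k - 1)^2`, `O` the observed contingency
#' proportions and `E` the chance-expected proportions (outer product of the
#' marginals). The weight matrix always uses the full fixed rating scale
#' (`levels`), so unobserved levels do not change the statistic's scale.
#'
#' @param r1,r2 rating vectors on a shared ordinal scale; pairs with any
#'   missing value are dropped.
#' @param levels the full ordinal scale (default -2..2).
#' @return kappa in \[-1, 1\], or `NA` with a warning when both raters are
#'   constant and identical (agreement is then undefined).
#' @export
cohen_kappa_quadratic <- function(r1, r2, levels = -2:2) {
  if (length(r1) != length(r2)) stop("rating vectors must have equal length")
  keep <- !is.na(r1) & !is.na(r2)
  r1 <- r1[keep]; r2 <- r2[keep]
  if (length(r1) < 2L) stop("need >= 2 pairwise-complete ratings")
  if (!all(c(r1, r2) %in% levels)) stop("ratings outside the declared scale")
  k <- length(levels)
  o <- table(factor(r1, levels = levels), factor(r2, levels = levels))
  o <- o / sum(o)
  e <- outer(rowSums(o), colSums(o))
  w <- outer(seq_len(k), seq_len(k), function(i, j) (i - j)^2 / (k - 1)^2)
  denom <- sum(w * e)
  if (denom == 0) {
    warning("kappa undefined: both raters constant and identical")
    return(NA_real_)
  }
  1 - sum(w * o) / denom
}

#' Pairwise kappa matrix over a panel of coders
#'
#' Computes quadratic-weighted kappa for every pair of coders. Additional
#' coders (e.g. a model's predictions mapped to the rating scale with
#' [score_to_rating()]) may be appended as extra columns.
#'
#' @param ratings participants x coders matrix on the rating scale.
#' @param extra_coders optional named list of rating vectors aligned to the
#'   participants.
#' @param levels the full ordinal scale.
#' @return symmetric matrix with unit diagonal; undefined cells are `NA`.
#' @export
pairwise_kappa_matrix <- function(ratings, extra_coders = NULL,
                                  levels = -2:2) {
  m <- as.matrix(ratings)
  if (!is.null(extra_coders)) {
    ec <- do.call(cbind, extra_coders)
    if (nrow(ec) != nrow(m)) stop("extra coders must align to participants")
    m <- cbind(m, ec)
  }
  if (ncol(m) < 2L) stop("need >= 2 coders")
  p <- ncol(m)
  out <- diag(1, p)
  dimnames(out) <- list(colnames(m), colnames(m))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      kap <- tryCatch(
        suppressWarnings(cohen_kappa_quadratic(m[, i], m[, j], levels)),
        error = function(e) NA_real_
      )
      out[i, j] <- out[j, i] <- kap
    }
  }
  out
}

#' Intraclass correlation (two-way mixed, consistency)
#'
#' ICC3 (single measure) and ICC3k (mean of k raters) from the two-way
#' ANOVA mean squares: `ICC3 = (MS_R - MS_E) / (MS_R + (k-1) MS_E)` and
#' `ICC3k = (MS_R - MS_E) / MS_R`, where `MS_R` is the between-participant
#' and `MS_E` the residual mean square. Confidence intervals use the
#' Shrout-Fleiss F-distribution bounds.
#'
#' ICC3k is appropriate when a fixed panel of k raters codes every
#' participant and the panel mean is the score of record; ICC3 when single
#' raters' scores must generalize.
#'
#' @param ratings participants x coders numeric matrix; rows with any
#'   missing value are dropped (listwise-complete).
#' @param variant `"ICC3"` or `"ICC3k"`.
#' @param ci_level confidence level.
#' @return list with `estimate`, `ci` (length-2), `variant`, `n`, `k`,
#'   `ms_rows`, `ms_error`.
#' @export
icc <- function(ratings, variant = c("ICC3", "ICC3k"), ci_level = 0.95) {
  variant <- match.arg(variant)
  m <- as.matrix(ratings)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 participants and >= 2 coders")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ss_rows < 1e-12 * max(ss_tot, 1)) {
    warning("degenerate variance: no between-participant variability; ICC set to 0")
    return(list(estimate = 0, ci = c(NA_real_, NA_real_), variant = variant,
                n = n, k = k, ms_rows = ms_r, ms_error = ms_e))
  }
  est <- if (variant == "ICC3") {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  } else {
    (ms_r - ms_e) / ms_r
  }
  alpha <- 1 - ci_level
  f <- ms_r / ms_e
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  fl <- f / stats::qf(1 - alpha / 2, df1, df2)
  fu <- f * stats::qf(1 - alpha / 2, df2, df1)
  ci <- if (variant == "ICC3") {
    c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    c(1 - 1 / fl, 1 - 1 / fu)
  }
  list(estimate = est, ci = ci, variant = variant, n = n, k = k,
       ms_rows = ms_r, ms_error = ms_e)
}

#' Treat a model as an additional coder
#'
#' Places model pass-probabilities on the same \[0,1\] scale as the scaled
#' expert ratings and appends them as an extra coder column, ready for
#' `icc(..., variant = "ICC3")`. Model scores stay continuous; they are not
#' re-discretized.
#'
#' @param probabilities model scores in \[0,1\], named by participant id or
#'   aligned to the rows of `experts`.
#' @param experts participants x experts rating matrix (-2..2 scale) with
#'   participant ids as rownames.
#' @return numeric matrix participants x (experts + 1) on the \[0,1\] scale,
#'   with the model as the last column.
#' @export
model_as_coder <- function(probabilities, experts) {
  experts <- as.matrix(experts)
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop("model probabilities must be in [0, 1]")
  }
  if (!is.null(names(probabilities)) && !is.null(rownames(experts))) {
    if (!setequal(names(probabilities), rownames(experts))) {
      stop("participant sets of model scores and expert ratings differ")
    }
    probabilities <- probabilities[rownames(experts)]
  } else if (length(probabilities) != nrow(experts)) {
    stop("model scores must align with the expert-rated participants")
  }
  out <- cbind((experts + 2) / 4, model = probabilities)
  colnames(out) <- c(colnames(experts), "model")
  out
}

#' Read / write ratings tables
#'
#' Long form is a CSV with columns `participant_id`, `rater_id`, `rating`;
#' wide form has one column per rater with empty cells for missing ratings.
#'
#' @param path CSV path.
#' @param ratings participants x raters matrix.
#' @return `read_ratings_wide` returns a matrix with participant rownames.
#' @export
read_ratings_wide <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("", "NA", "n/a"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_ratings_wide
#' @export
write_ratings_wide <- function(ratings, path) {
  df <- data.frame(participant_id = rownames(ratings), ratings,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_ratings_wide
#' @export
read_ratings_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("participant_id", "rater_id", "rating") %in% names(df)))
  df
}
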