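# Independent from-definition oracle implementations. These deliberately
# avoid contingency tables, rank identities and ANOVA shortcuts so that they
# exercise a different computational path than the package functions.

# Weighted kappa straight from its population definition: observed mean
# disagreement over paired ratings vs expected mean disagreement over all
# cross pairs.
oracle_kappa_quadratic <- function(r1, r2, levels = -2:2) {
  keep <- !is.na(r1) & !is.na(r2)
  r1 <- r1[keep]; r2 <- r2[keep]
  k <- length(levels)
  w <- function(a, b) {
    (match(a, levels) - match(b, levels))^2 / (k - 1)^2
  }
  n <- length(r1)
  obs <- mean(w(r1, r2))
  exp_d <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      exp_d <- exp_d + w(r1[i], r2[j])
    }
  }
  exp_d <- exp_d / n^2
  if (exp_d == 0) return(NA_real_)
  1 - obs / exp_d
}

# ICC3/ICC3k with mean squares taken from a fitted two-way ANOVA.
oracle_icc <- function(m, variant) {
  df <- data.frame(
    value = as.vector(m),
    participant = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  fit <- stats::aov(value ~ participant + rater, data = df)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  ms_r <- ms[1]; ms_e <- ms[3]
  k <- ncol(m)
  if (variant == "ICC3") (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  else (ms_r - ms_e) / ms_r
}

# ROC-AUC by enumerating every positive-negative pair.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) {
    for (q in neg) {
      conc <- conc + (p > q) + 0.5 * (p == q)
    }
  }
  conc / (length(pos) * length(neg))
}

# Exact Shapley values by subset enumeration, with the interventional value
# function v(S) = mean over background rows of f(x_S, bg_notS).
oracle_shapley_exact <- function(predict_fun, x_row, background) {
  d <- length(x_row)
  v <- function(subset) {
    z <- background
    for (j in subset) z[, j] <- x_row[j]
    mean(predict_fun(z))
  }
  phi <- numeric(d)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), d))
  for (j in seq_len(d)) {
    others <- setdiff(seq_len(d), j)
    ss <- subsets[!subsets[[j]], , drop = FALSE]
    for (r in seq_len(nrow(ss))) {
      s <- others[unlist(ss[r, others])]
      wgt <- factorial(length(s)) * factorial(d - length(s) - 1) / factorial(d)
      phi[j] <- phi[j] + wgt * (v(c(s, j)) - v(s))
    }
  }
  phi
}
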