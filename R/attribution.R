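#' Integrated-gradients attribution for the QC network
#'
#' Attributes the model's pass probability to every input voxel (and, for
#' metrics-augmented models, every metric) by integrating the input gradient
#' along the straight path from a baseline image to the input:
#' `attr_i = (x_i - b_i) * mean_k dF/dx_i` evaluated at
#' `b + alpha_k (x - b)`. The Riemann sum uses midpoint evaluation
#' (`alpha_k = (k - 1/2) / m`), which halves the discretization error of the
#' one-sided schemes at equal step count. The default baseline is the black
#' (all-zero) image, including the metrics channel when present.
#'
#' The completeness identity `sum(attr) = F(x) - F(baseline)` holds up to
#' the Riemann discretization; the residual is recorded as
#' `completeness_gap`.
#'
#' Positive attributions are evidence toward passing QC, negative toward
#' failing.
#'
#' @param model a trained `qc_cnn`, or a list with elements `value(x)` and
#'   `grad(x)` describing any differentiable scalar model (useful for
#'   verification against closed forms).
#' @param x input volume (D,H,W,C array) or, for a generic model, a numeric
#'   vector.
#' @param baseline same shape as `x`; default all zeros.
#' @param metrics metrics vector for metrics-augmented models.
#' @param metrics_baseline baseline for the metrics vector (default zeros).
#' @param m_steps number of Riemann steps (default 128).
#' @param batch_size forward/backward chunk size along the path.
#' @return object of class `attribution_map`: `attribution` (same shape as
#'   `x`), `metrics_attribution` (or NULL), `m_steps`, `baseline`
#'   description, `f_input`, `f_baseline`, `completeness_gap`.
#' @export
integrated_gradients <- function(model, x, baseline = NULL, metrics = NULL,
                                 metrics_baseline = NULL, m_steps = 128L,
                                 batch_size = 8L) {
  if (is.list(model) && !inherits(model, "qc_cnn")) {
    return(ig_generic(model, x, baseline, m_steps))
  }
  stopifnot(inherits(model, "qc_cnn"))
  if (is.null(baseline)) baseline <- array(0, dim = dim(x))
  if (!all(dim(baseline) == dim(x))) stop("baseline must match input shape")
  with_metrics <- model$spec$with_metrics
  if (with_metrics) {
    if (is.null(metrics)) stop("model requires a metrics vector")
    if (is.null(metrics_baseline)) metrics_baseline <- numeric(length(metrics))
  }
  alphas <- (seq_len(m_steps) - 0.5) / m_steps
  dx <- x - baseline
  dmet <- if (with_metrics) metrics - metrics_baseline else NULL
  grad_sum <- array(0, dim = dim(x))
  met_grad_sum <- if (with_metrics) numeric(length(metrics)) else NULL
  for (chunk in split(seq_len(m_steps), ceiling(seq_len(m_steps) / batch_size))) {
    vols <- lapply(alphas[chunk], function(a) baseline + a * dx)
    mets <- if (with_metrics) {
      do.call(rbind, lapply(alphas[chunk], function(a) {
        metrics_baseline + a * dmet
      }))
    } else NULL
    g <- qc_cnn_input_grad(model, vols, metrics = mets)
    for (j in seq_along(chunk)) {
      if (!all(is.finite(g$dx[[j]]))) {
        stop("non-finite gradient at interpolation step ", chunk[j])
      }
      grad_sum <- grad_sum + g$dx[[j]]
    }
    if (with_metrics) met_grad_sum <- met_grad_sum + colSums(g$dmetrics)
  }
  attribution <- dx * grad_sum / m_steps
  met_attr <- if (with_metrics) dmet * met_grad_sum / m_steps else NULL
  f_input <- predict_qc(model, x,
                        metrics = if (with_metrics) {
                          matrix(metrics, 1L)
                        } else NULL)
  f_base <- predict_qc(model, baseline,
                       metrics = if (with_metrics) {
                         matrix(metrics_baseline, 1L)
                       } else NULL)
  total <- sum(attribution) + if (with_metrics) sum(met_attr) else 0
  structure(
    list(attribution = attribution, metrics_attribution = met_attr,
         m_steps = m_steps,
         baseline = if (all(baseline == 0)) "black" else "custom",
         f_input = f_input, f_baseline = f_base,
         completeness_gap = abs(total - (f_input - f_base))),
    class = "attribution_map"
  )
}

# Generic path for a model given as value/gradient closures over a numeric
# vector input.
ig_generic <- function(model, x, baseline, m_steps) {
  if (is.null(baseline)) baseline <- x * 0
  alphas <- (seq_len(m_steps) - 0.5) / m_steps
  dx <- x - baseline
  grad_sum <- x * 0
  for (k in seq_len(m_steps)) {
    g <- model$grad(baseline + alphas[k] * dx)
    if (!all(is.finite(g))) {
      stop("non-finite gradient at interpolation step ", k)
    }
    grad_sum <- grad_sum + g
  }
  attribution <- dx * grad_sum / m_steps
  f_input <- model$value(x)
  f_base <- model$value(baseline)
  structure(
    list(attribution = attribution, metrics_attribution = NULL,
         m_steps = m_steps,
         baseline = if (all(baseline == 0)) "black" else "custom",
         f_input = f_input, f_baseline = f_base,
         completeness_gap = abs(sum(attribution) - (f_input - f_base))),
    class = "attribution_map"
  )
}

#' Select confusion-class exemplars
#'
#' Picks one deterministic exemplar per confusion class (TP, TN, FP, FN) at
#' the given threshold: the highest-confidence member of each class (largest
#' score for predicted-pass classes, smallest for predicted-fail classes),
#' with ties broken by participant id. Empty classes are reported with `NA`,
#' never fabricated.
#'
#' @param scores per-participant scores in \[0,1\].
#' @param labels binary ground truth.
#' @param threshold decision threshold (default 0.5; predictions are
#'   `score >= threshold`).
#' @param ids participant ids (default names of `scores` or indices).
#' @return data frame with rows TP, TN, FP, FN and columns
#'   `participant_id`, `score`, `label`.
#' @export
confusion_examples <- function(scores, labels, threshold = 0.5, ids = NULL) {
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (is.null(ids)) {
    ids <- if (!is.null(names(scores))) {
      names(scores)
    } else as.character(seq_along(scores))
  }
  pred <- as.integer(scores >= threshold)
  pick <- function(sel, decreasing) {
    ix <- which(sel)
    if (length(ix) == 0L) {
      return(data.frame(participant_id = NA_character_, score = NA_real_,
                        label = NA_integer_, stringsAsFactors = FALSE))
    }
    ord <- ix[order(scores[ix] * (if (decreasing) -1 else 1), ids[ix])]
    data.frame(participant_id = ids[ord[1]], score = scores[ord[1]],
               label = labels[ord[1]], stringsAsFactors = FALSE)
  }
  out <- rbind(
    TP = pick(pred == 1L & labels == 1L, decreasing = TRUE),
    TN = pick(pred == 0L & labels == 0L, decreasing = FALSE),
    FP = pick(pred == 1L & labels == 0L, decreasing = TRUE),
    FN = pick(pred == 0L & labels == 1L, decreasing = FALSE)
  )
  out$class <- rownames(out)
  out[, c("class", "participant_id", "score", "label")]
}

#' Display mask for an attribution map
#'
#' Keeps only the voxels whose absolute attribution strictly exceeds
#' `keep_fraction_threshold` times the maximum absolute attribution of the
#' image, mirroring the rendering convention in which voxels at or below
#' 98% of the peak are transparent.
#'
#' @param attr an `attribution_map` or a numeric array.
#' @param keep_fraction_threshold fraction of the peak magnitude.
#' @return logical array of the same shape; all-`FALSE` for an all-zero map.
#' @export
display_mask <- function(attr, keep_fraction_threshold = 0.98) {
  a <- if (inherits(attr, "attribution_map")) attr$attribution else attr
  if (!all(is.finite(a))) stop("attribution map must be finite")
  mx <- max(abs(a))
  if (mx == 0) {
    return(array(FALSE, dim = dim(a) %||% length(a)))
  }
  abs(a) > keep_fraction_threshold * mx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an attribution map as NIfTI with a JSON sidecar
#'
#' @param attr an `attribution_map`.
#' @param path output path without extension; writes `<path>.nii.gz` and
#'   `<path>.json`.
#' @export
write_attribution <- function(attr, path) {
  stopifnot(inherits(attr, "attribution_map"))
  RNifti::writeNifti(attr$attribution, paste0(path, ".nii.gz"))
  jsonlite::write_json(
    list(m_steps = attr$m_steps, baseline = attr$baseline,
         f_input = attr$f_input, f_baseline = attr$f_baseline,
         completeness_gap = attr$completeness_gap,
         metrics_attribution = attr$metrics_attribution),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
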