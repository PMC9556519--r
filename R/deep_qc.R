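#' Specify the 3D convolutional QC network
#'
#' Describes the image-based QC classifier: four convolutional blocks
#' (3x3x3 kernels, ReLU, 2x2x2 max pooling, batch normalization) with
#' 64, 64, 128 and 256 filters, global average pooling, optional
#' concatenation of a standardized vector of automated data-quality metrics
#' (followed by batch normalization), two fully connected layers of 512 and
#' 128 rectified-linear units each followed by 40% dropout, and a single
#' sigmoid output unit giving the probability of passing QC.
#'
#' Convolutions are zero-padded ("same"), so the trainable parameter count
#' does not depend on the input extents: global average pooling collapses the
#' spatial grid before the dense head. With 4 imaging channels and 31
#' metrics the network has exactly 1,438,783 trainable parameters.
#'
#' @param with_metrics logical; if `TRUE` the data-quality metrics vector is
#'   routed around the convolutional stack and concatenated with the pooled
#'   image features (the metrics-augmented variant).
#' @param n_imaging_channels number of input channels (default 4: the b=0
#'   volume and the x/y/z components of the directionally encoded color FA).
#' @param n_metrics length of the metrics vector (default 31).
#' @param input_dim integer vector of 3 spatial extents; every extent must be
#'   at least 16 so the grid survives four pooling halvings.
#' @param filters,fc_units,dropout,bn_momentum,bn_eps architecture
#'   hyperparameters; defaults follow the reference roster.
#' @return an object of class `qc_network_spec`.
#' @export
qc_network_spec <- function(with_metrics = FALSE, n_imaging_channels = 4L,
                            n_metrics = 31L, input_dim = c(32L, 32L, 32L),
                            filters = c(64L, 64L, 128L, 256L),
                            fc_units = c(512L, 128L), dropout = 0.4,
                            bn_momentum = 0.99, bn_eps = 1e-3) {
  input_dim <- as.integer(input_dim)
  if (length(input_dim) != 3L || any(is.na(input_dim))) {
    stop("`input_dim` must be three spatial extents")
  }
  if (any(input_dim < 16L)) {
    stop("input extents too small to survive 4 pooling halvings (need >= 16)")
  }
  if (length(filters) != 4L) stop("exactly 4 convolutional blocks are required")
  structure(
    list(
      with_metrics = isTRUE(with_metrics),
      n_imaging_channels = as.integer(n_imaging_channels),
      n_metrics = if (isTRUE(with_metrics)) as.integer(n_metrics) else 0L,
      input_dim = input_dim,
      filters = as.integer(filters),
      fc_units = as.integer(fc_units),
      dropout = dropout,
      bn_momentum = bn_momentum,
      bn_eps = bn_eps
    ),
    class = "qc_network_spec"
  )
}

#' Build the QC network
#'
#' Instantiates the network described by a [qc_network_spec()] with
#' Glorot-uniform weights, unit batch-norm scales and zero shifts.
#'
#' @param spec a `qc_network_spec`.
#' @param seed integer seed for weight initialization.
#' @return an object of class `qc_cnn` holding the parameters, the
#'   batch-norm running statistics and the (initially unset) metric
#'   standardization constants.
#' @seealso [n_trainable_parameters()], [train_qc_cnn()], [predict_qc()]
#' @export
build_qc_cnn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "qc_network_spec"))
  set.seed(seed)
  f <- spec$filters
  cin <- c(spec$n_imaging_channels, f[-4])
  params <- list()
  state <- list()
  for (i in 1:4) {
    k <- 27L * cin[i]
    # Glorot fans for a conv kernel: receptive field x channels
    params[[paste0("cw", i)]] <- glorot_uniform(k, 27L * f[i], k, f[i])
    params[[paste0("cb", i)]] <- numeric(f[i])
    params[[paste0("g", i)]] <- rep(1, f[i])
    params[[paste0("be", i)]] <- numeric(f[i])
    state[[paste0("rm", i)]] <- numeric(f[i])
    state[[paste0("rv", i)]] <- rep(1, f[i])
  }
  p <- f[4] + spec$n_metrics
  params$g5 <- rep(1, p)
  params$be5 <- numeric(p)
  state$rm5 <- numeric(p)
  state$rv5 <- rep(1, p)
  params$fw1 <- glorot_uniform(p, spec$fc_units[1], p, spec$fc_units[1])
  params$fb1 <- numeric(spec$fc_units[1])
  params$fw2 <- glorot_uniform(spec$fc_units[1], spec$fc_units[2],
                               spec$fc_units[1], spec$fc_units[2])
  params$fb2 <- numeric(spec$fc_units[2])
  params$ow <- glorot_uniform(spec$fc_units[2], 1L, spec$fc_units[2], 1L)
  params$ob <- numeric(1)
  state$metrics_center <- NULL
  state$metrics_scale <- NULL
  structure(list(spec = spec, params = params, state = state),
            class = "qc_cnn")
}

#' Count trainable parameters
#'
#' Convolution and dense weights and biases plus batch-norm scale and shift
#' vectors; batch-norm running statistics are not trainable and are excluded.
#'
#' @param model a `qc_cnn`.
#' @return integer parameter count.
#' @export
n_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "qc_cnn"))
  sum(vapply(model$params, length, numeric(1)))
}

## ---- input plumbing ----

# Accepts a list of (D,H,W,C) arrays or a single (D,H,W,C,B) array and
# returns a list of V x C activation matrices.
as_vol_list <- function(volumes, spec) {
  if (is.array(volumes) && length(dim(volumes)) == 5L) {
    volumes <- lapply(seq_len(dim(volumes)[5]), function(b) {
      volumes[, , , , b, drop = TRUE]
    })
  }
  if (is.array(volumes) && length(dim(volumes)) == 4L) volumes <- list(volumes)
  if (!is.list(volumes)) stop("volumes must be 4D arrays or a list of them")
  lapply(volumes, function(v) {
    d <- dim(v)
    if (length(d) != 4L || !all(d[1:3] == spec$input_dim) ||
        d[4] != spec$n_imaging_channels) {
      stop(sprintf(
        "volume shape mismatch: expected %s x %d channels, got %s",
        paste(spec$input_dim, collapse = "x"), spec$n_imaging_channels,
        paste(d, collapse = "x")
      ))
    }
    dim(v) <- c(prod(d[1:3]), d[4])
    v
  })
}

standardize_metrics <- function(model, mets) {
  if (!model$spec$with_metrics) return(NULL)
  if (is.null(mets)) stop("this model requires a metrics matrix")
  mets <- as.matrix(mets)
  if (ncol(mets) != model$spec$n_metrics) {
    stop(sprintf("expected %d metric columns, got %d",
                 model$spec$n_metrics, ncol(mets)))
  }
  if (is.null(model$state$metrics_center)) {
    stop("model has no metric standardization constants; train it first")
  }
  sweep(sweep(mets, 2L, model$state$metrics_center), 2L,
        model$state$metrics_scale, `/`)
}

## ---- full-network forward / backward ----

qc_cnn_forward <- function(model, x_list, mets_std, training,
                           dropout_masks = NULL) {
  sp <- model$spec
  pm <- model$params
  st <- model$state
  b <- length(x_list)
  dims <- sp$input_dim
  cache <- list(n = b)
  cur <- x_list
  for (i in 1:4) {
    cb <- conv_block_forward(cur, pm[[paste0("cw", i)]], pm[[paste0("cb", i)]],
                             dims)
    s <- do.call(rbind, cb$y_list)
    bn <- bn_forward(s, pm[[paste0("g", i)]], pm[[paste0("be", i)]],
                     sp$bn_eps, training,
                     st[[paste0("rm", i)]], st[[paste0("rv", i)]],
                     sp$bn_momentum)
    st[[paste0("rm", i)]] <- bn$run_mean
    st[[paste0("rv", i)]] <- bn$run_var
    v2 <- prod(cb$out_dims)
    cache[[paste0("blk", i)]] <- list(
      x_list = cur, idx_list = cb$idx_list, pooled = s, bn = bn$cache,
      dims = dims, out_dims = cb$out_dims, v2 = v2
    )
    cur <- lapply(seq_len(b), function(j) {
      bn$y[((j - 1) * v2 + 1):(j * v2), , drop = FALSE]
    })
    dims <- cb$out_dims
  }
  v4 <- prod(dims)
  gap <- t(vapply(cur, colMeans, numeric(sp$filters[4])))
  cache$v4 <- v4
  g <- if (sp$with_metrics) cbind(gap, mets_std) else gap
  bn5 <- bn_forward(g, pm$g5, pm$be5, sp$bn_eps, training, st$rm5, st$rv5,
                    sp$bn_momentum)
  st$rm5 <- bn5$run_mean
  st$rv5 <- bn5$run_var
  cache$bn5 <- bn5$cache
  h <- bn5$y
  if (training) {
    if (is.null(dropout_masks)) {
      keep <- 1 - sp$dropout
      dropout_masks <- list(
        m1 = matrix(stats::rbinom(b * sp$fc_units[1], 1L, keep) / keep,
                    b, sp$fc_units[1]),
        m2 = matrix(stats::rbinom(b * sp$fc_units[2], 1L, keep) / keep,
                    b, sp$fc_units[2])
      )
    }
  } else {
    dropout_masks <- list(m1 = 1, m2 = 1)
  }
  z1 <- sweep(h %*% pm$fw1, 2L, pm$fb1, `+`)
  a1 <- pmax(z1, 0) * dropout_masks$m1
  z2 <- sweep(a1 %*% pm$fw2, 2L, pm$fb2, `+`)
  a2 <- pmax(z2, 0) * dropout_masks$m2
  logit <- as.numeric(a2 %*% pm$ow) + pm$ob
  cache$h <- h
  cache$z1 <- z1; cache$a1 <- a1
  cache$z2 <- z2; cache$a2 <- a2
  cache$masks <- dropout_masks
  cache$training <- training
  list(p = sigmoid(logit), cache = cache, state = st)
}

qc_cnn_backward <- function(model, cache, dlogit, need_input_grad = FALSE) {
  sp <- model$spec
  pm <- model$params
  b <- cache$n
  grads <- list()
  dlogit <- matrix(dlogit, ncol = 1)
  grads$ow <- crossprod(cache$a2, dlogit)
  grads$ob <- sum(dlogit)
  da2 <- (dlogit %*% t(pm$ow)) * cache$masks$m2
  dz2 <- da2 * (cache$z2 > 0)
  grads$fw2 <- crossprod(cache$a1, dz2)
  grads$fb2 <- colSums(dz2)
  da1 <- tcrossprod(dz2, pm$fw2) * cache$masks$m1
  dz1 <- da1 * (cache$z1 > 0)
  grads$fw1 <- crossprod(cache$h, dz1)
  grads$fb1 <- colSums(dz1)
  dh <- tcrossprod(dz1, pm$fw1)
  if (cache$training) {
    bnb <- bn_backward(dh, pm$g5, cache$bn5)
    grads$g5 <- bnb$dgamma
    grads$be5 <- bnb$dbeta
    dg <- bnb$dx
  } else {
    grads$g5 <- numeric(length(pm$g5))
    grads$be5 <- numeric(length(pm$be5))
    dg <- bn_backward_infer(dh, cache$bn5)
  }
  nf <- sp$filters[4]
  dgap <- dg[, seq_len(nf), drop = FALSE]
  dmetrics <- if (sp$with_metrics) {
    dg[, -seq_len(nf), drop = FALSE]
  } else NULL
  v4 <- cache$v4
  dcur <- lapply(seq_len(b), function(j) {
    matrix(dgap[j, ], v4, nf, byrow = TRUE) / v4
  })
  dx_list <- NULL
  for (i in 4:1) {
    blk <- cache[[paste0("blk", i)]]
    ds <- do.call(rbind, dcur)
    if (cache$training) {
      bnb <- bn_backward(ds, pm[[paste0("g", i)]], blk$bn)
      grads[[paste0("g", i)]] <- bnb$dgamma
      grads[[paste0("be", i)]] <- bnb$dbeta
      dpool <- bnb$dx
    } else {
      grads[[paste0("g", i)]] <- numeric(length(pm[[paste0("g", i)]]))
      grads[[paste0("be", i)]] <- numeric(length(pm[[paste0("be", i)]]))
      dpool <- bn_backward_infer(ds, blk$bn)
    }
    dpool <- dpool * (blk$pooled > 0)  # ReLU derivative at the pooled maxima
    dy_list <- lapply(seq_len(b), function(j) {
      dpool[((j - 1) * blk$v2 + 1):(j * blk$v2), , drop = FALSE]
    })
    cbb <- conv_block_backward(dy_list, blk$idx_list, blk$x_list,
                               pm[[paste0("cw", i)]], blk$dims,
                               need_dx = (i > 1L || need_input_grad))
    grads[[paste0("cw", i)]] <- cbb$dw
    grads[[paste0("cb", i)]] <- cbb$db
    if (i > 1L) dcur <- cbb$dx_list else dx_list <- cbb$dx_list
  }
  list(grads = grads[names(pm)], dx_list = dx_list, dmetrics = dmetrics)
}

# Gradient of the sigmoid output with respect to the input volume (and the
# metrics vector, when present), evaluated in inference mode. Used by the
# integrated-gradients attribution.
qc_cnn_input_grad <- function(model, volume, metrics = NULL) {
  x_list <- as_vol_list(volume, model$spec)
  mets_std <- if (model$spec$with_metrics) {
    if (!is.matrix(metrics)) {
      metrics <- matrix(metrics, nrow = length(x_list),
                        ncol = model$spec$n_metrics, byrow = TRUE)
    }
    standardize_metrics(model, metrics)
  } else NULL
  fw <- qc_cnn_forward(model, x_list, mets_std, training = FALSE)
  p <- fw$p
  dlogit <- p * (1 - p)  # d sigmoid / d logit
  bw <- qc_cnn_backward(model, fw$cache, dlogit, need_input_grad = TRUE)
  dx <- lapply(bw$dx_list, function(m) {
    dim(m) <- c(model$spec$input_dim, model$spec$n_imaging_channels)
    m
  })
  dmet <- if (!is.null(bw$dmetrics)) {
    # chain through the stored standardization
    sweep(bw$dmetrics, 2L, model$state$metrics_scale, `/`)
  } else NULL
  list(p = p, dx = dx, dmetrics = dmet)
}

## ---- training ----

#' Train the QC network
#'
#' Optimizes binary cross-entropy with Adam at an initial learning rate of
#' 1e-4. The learning rate is halved when the validation loss plateaus for
#' more than two epochs, and training stops early when the validation loss
#' fails to improve by more than 0.001 for twenty consecutive epochs; the
#' weights from the best validation epoch are restored.
#'
#' Continuous targets in \[0,1\] (e.g. amplified QC scores) are binarized at
#' 0.5 before entering the loss. Data-quality metrics, when the model uses
#' them, are standardized to zero mean and unit variance on the training
#' split; the constants are stored in the model for prediction time.
#'
#' @param model a `qc_cnn` from [build_qc_cnn()].
#' @param volumes list of (D,H,W,C) arrays (or a 5D array) matching the spec.
#' @param targets numeric vector of QC scores in \[0,1\] or binary labels.
#' @param metrics optional participants x metrics matrix (required iff the
#'   model was built `with_metrics`).
#' @param validation_fraction fraction held out (stratified) for the
#'   validation loss driving the schedule; must leave a non-empty split.
#' @param max_epochs,batch_size,learning_rate training configuration.
#' @param seed integer seed controlling the split, shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return list with elements `model` (trained) and `history` (a data frame
#'   with per-epoch training/validation loss, accuracy, ROC-AUC and the
#'   learning-rate trace; attributes `stopped_epoch` and `best_epoch`).
#' @export
train_qc_cnn <- function(model, volumes, targets, metrics = NULL,
                         validation_fraction = 0.2, max_epochs = 50L,
                         batch_size = 8L, learning_rate = 1e-4,
                         seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "qc_cnn"))
  x_all <- as_vol_list(volumes, model$spec)
  y <- as.numeric(targets >= 0.5)
  n <- length(x_all)
  if (length(y) != n) stop("targets must align with volumes")
  if (length(unique(y)) < 2L) stop("both classes must be present in targets")
  set.seed(seed)
  val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
    sample(ix, max(1L, round(length(ix) * validation_fraction)))
  }), use.names = FALSE)
  if (length(val_idx) == 0L || length(val_idx) == n) {
    stop("validation split is empty or consumes all data")
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  mets_all <- NULL
  if (model$spec$with_metrics) {
    if (is.null(metrics)) stop("model requires `metrics`")
    metrics <- as.matrix(metrics)
    ctr <- colMeans(metrics[tr_idx, , drop = FALSE])
    scl <- apply(metrics[tr_idx, , drop = FALSE], 2L, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    model$state$metrics_center <- ctr
    model$state$metrics_scale <- scl
    mets_all <- standardize_metrics(model, metrics)
  }

  opt <- adam_init(model$params)
  mon <- new_training_monitor(learning_rate)
  history <- list()
  best <- list(params = model$params, state = model$state, loss = Inf)

  eval_split <- function(idx) {
    ps <- numeric(length(idx))
    for (s in split(seq_along(idx), ceiling(seq_along(idx) / batch_size))) {
      fw <- qc_cnn_forward(
        model, x_all[idx[s]],
        if (is.null(mets_all)) NULL else mets_all[idx[s], , drop = FALSE],
        training = FALSE
      )
      ps[s] <- fw$p
    }
    ps
  }

  for (epoch in seq_len(max_epochs)) {
    ord <- sample(tr_idx)
    tr_loss <- c(); tr_p <- numeric(0); tr_y <- numeric(0)
    for (s in split(ord, ceiling(seq_along(ord) / batch_size))) {
      fw <- qc_cnn_forward(
        model, x_all[s],
        if (is.null(mets_all)) NULL else mets_all[s, , drop = FALSE],
        training = TRUE
      )
      model$state <- fw$state
      p <- fw$p
      yb <- y[s]
      tr_loss <- c(tr_loss, bce_loss(p, yb))
      tr_p <- c(tr_p, p); tr_y <- c(tr_y, yb)
      dlogit <- (p - yb) / length(s)
      bw <- qc_cnn_backward(model, fw$cache, dlogit)
      upd <- adam_step(model$params, bw$grads, opt, mon$lr)
      model$params <- upd$params
      opt <- upd$state
    }
    val_p <- eval_split(val_idx)
    val_y <- y[val_idx]
    vloss <- bce_loss(val_p, val_y)
    history[[epoch]] <- data.frame(
      epoch = epoch,
      loss = mean(tr_loss),
      accuracy = mean((tr_p >= 0.5) == tr_y),
      auc = if (length(unique(tr_y)) > 1) roc_auc(tr_y, tr_p) else NA_real_,
      val_loss = vloss,
      val_accuracy = mean((val_p >= 0.5) == val_y),
      val_auc = if (length(unique(val_y)) > 1) roc_auc(val_y, val_p)
                else NA_real_,
      lr = mon$lr
    )
    mon <- monitor_update(mon, vloss)
    if (vloss < best$loss) {
      best <- list(params = model$params, state = model$state, loss = vloss)
    }
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f val_loss %.4f val_auc %.3f lr %g",
                      epoch, mean(tr_loss), vloss,
                      history[[epoch]]$val_auc, mon$lr))
    }
    if (mon$stop) break
  }
  model$params <- best$params
  model$state <- best$state
  history <- do.call(rbind, history)
  attr(history, "stopped_epoch") <- mon$epoch
  attr(history, "best_epoch") <- which.min(history$val_loss)
  list(model = model, history = history)
}

#' Predict QC pass probabilities
#'
#' A single model returns its sigmoid output; a list of replicate models
#' (e.g. trained on different splits) returns the arithmetic mean of their
#' probabilities.
#'
#' @param models a `qc_cnn` or a list of them.
#' @param volumes volumes as in [train_qc_cnn()].
#' @param metrics optional metrics matrix for metrics-augmented models.
#' @param batch_size forward-pass chunk size.
#' @return numeric vector of pass probabilities in \[0,1\].
#' @export
predict_qc <- function(models, volumes, metrics = NULL, batch_size = 8L) {
  if (inherits(models, "qc_cnn")) models <- list(models)
  stopifnot(all(vapply(models, inherits, logical(1), "qc_cnn")))
  x_all <- as_vol_list(volumes, models[[1]]$spec)
  n <- length(x_all)
  acc <- numeric(n)
  for (m in models) {
    mets_std <- if (m$spec$with_metrics) {
      standardize_metrics(m, metrics)
    } else NULL
    p <- numeric(n)
    for (s in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
      fw <- qc_cnn_forward(
        m, x_all[s],
        if (is.null(mets_std)) NULL else mets_std[s, , drop = FALSE],
        training = FALSE
      )
      p[s] <- fw$p
    }
    acc <- acc + p
  }
  acc / length(models)
}

#' Train replicate QC networks
#'
#' Trains one network per seed on different training/validation splits and
#' returns the models and their histories. [predict_qc()] on the resulting
#' list averages the replicate probabilities.
#'
#' @param spec a `qc_network_spec`.
#' @param volumes,targets,metrics,... forwarded to [train_qc_cnn()].
#' @param seeds integer vector; one replicate per seed.
#' @return list with `models` and `histories`.
#' @export
train_qc_cnn_replicates <- function(spec, volumes, targets, metrics = NULL,
                                    seeds = 1:10, ...) {
  fits <- lapply(seeds, function(s) {
    train_qc_cnn(build_qc_cnn(spec, seed = s), volumes, targets,
                 metrics = metrics, seed = s, ...)
  })
  list(models = lapply(fits, `[[`, "model"),
       histories = lapply(fits, `[[`, "history"))
}

#' Save / load a trained QC network
#'
#' The checkpoint directory holds the parameter arrays (`weights.rds`) and a
#' JSON sidecar describing the architecture.
#'
#' @param model a `qc_cnn`.
#' @param path checkpoint directory (created if absent).
#' @return `save_qc_cnn` returns `path` invisibly; `load_qc_cnn` returns the
#'   restored `qc_cnn`.
#' @export
save_qc_cnn <- function(model, path) {
  stopifnot(inherits(model, "qc_cnn"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$spec),
                       file.path(path, "spec.json"), auto_unbox = TRUE)
  saveRDS(list(params = model$params, state = model$state),
          file.path(path, "weights.rds"))
  invisible(path)
}

#' @rdname save_qc_cnn
#' @export
load_qc_cnn <- function(path) {
  spec_l <- jsonlite::read_json(file.path(path, "spec.json"),
                                simplifyVector = TRUE)
  spec <- qc_network_spec(
    with_metrics = spec_l$with_metrics,
    n_imaging_channels = spec_l$n_imaging_channels,
    n_metrics = max(spec_l$n_metrics, 1L),
    input_dim = spec_l$input_dim,
    filters = spec_l$filters, fc_units = spec_l$fc_units,
    dropout = spec_l$dropout, bn_momentum = spec_l$bn_momentum,
    bn_eps = spec_l$bn_eps
  )
  w <- readRDS(file.path(path, "weights.rds"))
  structure(list(spec = spec, params = w$params, state = w$state),
            class = "qc_cnn")
}
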