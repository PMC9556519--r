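# Internal engine for the 3D convolutional QC network.
#
# Activations flow as matrices with rows = voxels (column-major over the
# spatial grid) and columns = channels, so a V x C matrix is memory-identical
# to a (D, H, W, C) array and channel-wise batch statistics are column
# statistics. Convolutions are im2col + BLAS matrix products (Rcpp kernels in
# src/kernels.cpp); gradients only ever flow through max-pool argmax
# positions, which keeps the backward pass sparse and memory-light.

glorot_uniform <- function(fan_in, fan_out, nrow, ncol) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -limit, limit), nrow, ncol)
}

#' @keywords internal
sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## ---- batch normalization (column-wise over an N x C matrix) ----

bn_forward <- function(x, gamma, beta, eps, training, run_mean, run_var,
                       momentum) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    v <- colMeans(xc * xc)
    ivar <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, ivar, `*`)
    n <- nrow(x)
    unbias <- if (n > 1) n / (n - 1) else 1
    list(
      y = sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`),
      cache = list(xc = xc, ivar = ivar, xhat = xhat),
      run_mean = momentum * run_mean + (1 - momentum) * mu,
      run_var = momentum * run_var + (1 - momentum) * v * unbias
    )
  } else {
    ivar <- 1 / sqrt(run_var + eps)
    xhat <- sweep(sweep(x, 2L, run_mean), 2L, ivar, `*`)
    list(
      y = sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`),
      cache = list(ivar = ivar, gamma = gamma),
      run_mean = run_mean, run_var = run_var
    )
  }
}

bn_backward <- function(dy, gamma, cache) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, `*`)
  dvar <- colSums(dxhat * cache$xc) * (-0.5) * cache$ivar^3
  dmu <- -colSums(dxhat) * cache$ivar - dvar * 2 * colMeans(cache$xc)
  dx <- sweep(dxhat, 2L, cache$ivar, `*`) +
    sweep(cache$xc, 2L, 2 * dvar / n, `*`) +
    matrix(dmu / n, n, length(dmu), byrow = TRUE)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_backward_infer <- function(dy, cache) {
  sweep(dy, 2L, cache$gamma * cache$ivar, `*`)
}

## ---- conv block: conv(k=3, same) + ReLU + maxpool(2) ----

conv_block_forward <- function(x_list, w, b, dims) {
  D <- dims[1]; H <- dims[2]; W <- dims[3]
  cin <- ncol(x_list[[1]])
  out <- lapply(x_list, function(x) {
    col <- im2col3d(as.numeric(x), D, H, W, cin, 3L)
    z <- col %*% w
    z <- sweep(z, 2L, b, `+`)
    z[z < 0] <- 0
    mp <- maxpool3d_fwd(as.numeric(z), D, H, W, ncol(w))
    dim(mp$y) <- c(length(mp$y) / ncol(w), ncol(w))
    list(y = mp$y, idx = mp$idx)
  })
  list(
    y_list = lapply(out, `[[`, "y"),
    idx_list = lapply(out, `[[`, "idx"),
    out_dims = dims %/% 2L
  )
}

# dy_list: per-sample gradient at the pooled output (V2 x C), already masked
# by the ReLU derivative (pooled value > 0). idx_list: argmax indices from the
# forward pass.
conv_block_backward <- function(dy_list, idx_list, x_list, w, dims, need_dx) {
  D <- dims[1]; H <- dims[2]; W <- dims[3]
  cin <- ncol(x_list[[1]])
  cout <- ncol(w)
  dw <- matrix(0, nrow(w), cout)
  db <- numeric(cout)
  dx_list <- if (need_dx) vector("list", length(x_list)) else NULL
  for (i in seq_along(x_list)) {
    dz <- maxpool3d_bwd(as.numeric(dy_list[[i]]), idx_list[[i]], D, H, W, cout)
    dim(dz) <- c(D * H * W, cout)
    col <- im2col3d(as.numeric(x_list[[i]]), D, H, W, cin, 3L)
    dw <- dw + crossprod(col, dz)
    db <- db + colSums(dz)
    if (need_dx) {
      dcol <- tcrossprod(dz, w)
      dx <- col2im3d(dcol, D, H, W, cin, 3L)
      dim(dx) <- c(D * H * W, cin)
      dx_list[[i]] <- dx
    }
  }
  list(dw = dw, db = db, dx_list = dx_list)
}

## ---- flat parameter-tree helpers (Adam) ----

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- training callbacks ----

# Learning-rate plateau reduction and early stopping, kept as a pure state
# machine so the schedule rules can be exercised on constructed loss traces.
new_training_monitor <- function(lr, lr_factor = 0.5, lr_patience = 2L,
                                 lr_min_delta = 1e-4,
                                 stop_min_delta = 0.001, stop_patience = 20L) {
  list(
    lr = lr, lr_factor = lr_factor, lr_patience = lr_patience,
    lr_min_delta = lr_min_delta,
    stop_min_delta = stop_min_delta, stop_patience = stop_patience,
    best_plateau = Inf, plateau_wait = 0L,
    best_stop = Inf, stop_wait = 0L,
    best_epoch = 0L, epoch = 0L, stop = FALSE, restore_best = FALSE
  )
}

monitor_update <- function(mon, val_loss) {
  mon$epoch <- mon$epoch + 1L
  # plateau LR schedule
  if (val_loss < mon$best_plateau - mon$lr_min_delta) {
    mon$best_plateau <- val_loss
    mon$plateau_wait <- 0L
  } else {
    mon$plateau_wait <- mon$plateau_wait + 1L
    if (mon$plateau_wait > mon$lr_patience) {
      mon$lr <- mon$lr * mon$lr_factor
      mon$plateau_wait <- 0L
      mon$best_plateau <- val_loss
    }
  }
  # early stopping on minimum improvement
  if (val_loss < mon$best_stop - mon$stop_min_delta) {
    mon$best_stop <- val_loss
    mon$best_epoch <- mon$epoch
    mon$stop_wait <- 0L
    mon$restore_best <- TRUE
  } else {
    mon$stop_wait <- mon$stop_wait + 1L
    mon$restore_best <- FALSE
    if (mon$stop_wait >= mon$stop_patience) mon$stop <- TRUE
  }
  mon
}
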