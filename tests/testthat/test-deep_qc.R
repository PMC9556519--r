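test_that("metrics-augmented network has exactly 1,438,783 parameters", {
  model <- build_qc_cnn(qc_network_spec(with_metrics = TRUE,
                                        n_imaging_channels = 4,
                                        n_metrics = 31))
  expect_identical(as.integer(n_trainable_parameters(model)), 1438783L)
  # extent-invariant thanks to global average pooling
  m2 <- build_qc_cnn(qc_network_spec(with_metrics = TRUE,
                                     input_dim = c(48, 32, 16)))
  expect_equal(n_trainable_parameters(m2), 1438783)
})

test_that("imaging-only parameter count matches layer-by-layer accounting", {
  model <- build_qc_cnn(qc_network_spec(with_metrics = FALSE))
  f <- c(64, 64, 128, 256)
  cin <- c(4, f[-4])
  conv <- sum(27 * cin * f + f)
  bn <- sum(2 * f) + 2 * f[4]          # per-block BN + post-pooling BN
  fc <- (f[4] * 512 + 512) + (512 * 128 + 128) + (128 + 1)
  expect_equal(n_trainable_parameters(model), conv + bn + fc)
})

test_that("network specification validates its preconditions", {
  expect_error(qc_network_spec(input_dim = c(8, 32, 32)), "pooling halvings")
  expect_error(qc_network_spec(input_dim = c(32, 32)), "three spatial")
  expect_error(qc_network_spec(filters = c(64, 64)), "4 convolutional")
})

test_that("forward pass on a zero volume is a finite probability", {
  spec <- qc_network_spec(with_metrics = FALSE, input_dim = c(16, 16, 16))
  model <- build_qc_cnn(spec, seed = 1)
  p <- predict_qc(model, array(0, c(16, 16, 16, 4)))
  expect_true(is.finite(p) && p > 0 && p < 1)
  expect_error(predict_qc(model, array(0, c(16, 16, 8, 4))), "shape mismatch")
})

test_that("backpropagation matches finite differences through all layer types", {
  spec <- qc_network_spec(with_metrics = TRUE, input_dim = c(16, 16, 16),
                          n_metrics = 3)
  model <- build_qc_cnn(spec, seed = 3)
  set.seed(9)
  xs <- lapply(1:2, function(i) array(runif(16^3 * 4), c(16, 16, 16, 4)))
  mets <- matrix(rnorm(6), 2, 3)
  y <- c(1, 0)
  xl <- hybridqc:::as_vol_list(xs, spec)
  masks <- list(m1 = matrix(1, 2, 512), m2 = matrix(1, 2, 128))
  fw <- hybridqc:::qc_cnn_forward(model, xl, mets, training = TRUE,
                                  dropout_masks = masks)
  bw <- hybridqc:::qc_cnn_backward(model, fw$cache, (fw$p - y) / 2)
  eps <- 1e-5
  for (nm in c("cw2", "g1", "fw2", "be5")) {
    i <- 1L
    num <- vapply(c(eps, -eps), function(h) {
      m2 <- model
      m2$params[[nm]][i] <- m2$params[[nm]][i] + h
      fw2 <- hybridqc:::qc_cnn_forward(m2, xl, mets, training = TRUE,
                                       dropout_masks = masks)
      hybridqc:::bce_loss(fw2$p, y)
    }, numeric(1))
    expect_equal(bw$grads[[nm]][i], (num[1] - num[2]) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("plateau and early-stopping rules fire on constructed loss traces", {
  # validation loss exactly flat: LR halves after patience, training stops
  # after twenty non-improving epochs
  mon <- hybridqc:::new_training_monitor(lr = 1e-4)
  stopped_at <- NA
  for (e in 1:40) {
    mon <- hybridqc:::monitor_update(mon, 0.7)
    if (mon$stop) {
      stopped_at <- e
      break
    }
  }
  # epoch 1 establishes the baseline; twenty non-improving epochs follow
  expect_equal(stopped_at, 21L)
  expect_lt(mon$lr, 1e-4)  # plateau rule fired along the way
  # first reduction happens after more than two plateau epochs
  mon2 <- hybridqc:::new_training_monitor(lr = 1e-4)
  lrs <- vapply(1:4, function(e) {
    mon2 <<- hybridqc:::monitor_update(mon2, 0.7)
    mon2$lr
  }, numeric(1))
  expect_equal(lrs, c(1e-4, 1e-4, 1e-4, 5e-5))
  # improvements above min_delta reset the stopping counter
  mon3 <- hybridqc:::new_training_monitor(lr = 1e-4)
  losses <- c(1, 0.9, 0.8995, rep(0.899, 25))  # second step below min_delta
  stops <- vapply(losses, function(l) {
    mon3 <<- hybridqc:::monitor_update(mon3, l)
    mon3$stop
  }, logical(1))
  # the sub-threshold improvement at epoch 3 starts the non-improving run
  expect_equal(which(stops)[1], 22L)
})

test_that("training on a tiny separable phantom set reduces the loss", {
  fit <- tiny_cnn_fit()$fit
  h <- fit$history
  expect_true(all(is.finite(unlist(h[, c("loss", "val_loss")]))))
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_true(all(diff(h$lr) <= 0))  # learning rate never increases
  expect_lte(nrow(h), 2)
})

test_that("training is reproducible under a fixed seed", {
  ph <- phantom_set(12, shape = c(16L, 16L, 16L), seed = 3)
  spec <- qc_network_spec(with_metrics = FALSE, input_dim = c(16, 16, 16))
  f1 <- train_qc_cnn(build_qc_cnn(spec, seed = 5), ph$volumes, ph$labels,
                     max_epochs = 1, batch_size = 4, seed = 5)
  f2 <- train_qc_cnn(build_qc_cnn(spec, seed = 5), ph$volumes, ph$labels,
                     max_epochs = 1, batch_size = 4, seed = 5)
  expect_equal(f1$history, f2$history)
  expect_equal(predict_qc(f1$model, ph$volumes[1:2]),
               predict_qc(f2$model, ph$volumes[1:2]))
})

test_that("replicate prediction averages probabilities", {
  fit <- tiny_cnn_fit()
  vols <- fit$phantoms$volumes[1:4]
  single <- predict_qc(fit$fit$model, vols)
  expect_equal(predict_qc(list(fit$fit$model, fit$fit$model, fit$fit$model),
                          vols), single)
  expect_true(all(single >= 0 & single <= 1))
})

test_that("training validates its inputs", {
  ph <- phantom_set(8, shape = c(16L, 16L, 16L), seed = 4)
  spec <- qc_network_spec(with_metrics = FALSE, input_dim = c(16, 16, 16))
  model <- build_qc_cnn(spec, seed = 1)
  expect_error(train_qc_cnn(model, ph$volumes, rep(1, 8)), "both classes")
  expect_error(
    train_qc_cnn(model, ph$volumes, ph$labels, validation_fraction = 1),
    "validation split"
  )
  m_iq <- build_qc_cnn(qc_network_spec(with_metrics = TRUE,
                                       input_dim = c(16, 16, 16)), seed = 1)
  expect_error(train_qc_cnn(m_iq, ph$volumes, ph$labels), "requires")
})

test_that("checkpoints restore an identical model", {
  fit <- tiny_cnn_fit()
  dir <- tempfile()
  save_qc_cnn(fit$fit$model, dir)
  m2 <- load_qc_cnn(dir)
  vols <- fit$phantoms$volumes[1:3]
  expect_equal(predict_qc(m2, vols), predict_qc(fit$fit$model, vols))
})
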