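tiny_training_set <- function(n = 4L, side = 16L) {
  cfg <- tiny_phantom_config(side)
  lapply(seq_len(n) - 1L, function(i) {
    ph <- generate_slice(cfg, "tr", i)
    list(x = preprocess_slice(ph$image, side = side), y = ph$liver_mask)
  })
}

test_that("zero-epoch training is a no-op returning untouched weights", {
  net <- build_aim_unet(tiny_network_config())
  w0 <- init_weights(net, 5)
  fit <- train(net, tiny_training_set(2),
               train_config(epochs = 0, seed = 5), weights = w0)
  expect_identical(fit$weights, w0)
  expect_equal(nrow(fit$history), 0)
  expect_equal(fit$steps, 0L)
})

test_that("training rejects bad inputs before any optimisation", {
  net <- build_aim_unet(tiny_network_config())
  expect_error(train(net, list(), train_config()), "empty")
  raw <- list(list(x = matrix(50, 16, 16), y = matrix(0, 16, 16)))
  expect_error(train(net, raw, train_config()), "normalize")
  wrong_size <- list(list(x = matrix(0.5, 8, 8), y = matrix(0, 8, 8)))
  expect_error(train(net, wrong_size, train_config()), "input size")
})

test_that("identical seeds reproduce the first-epoch loss exactly", {
  net <- build_aim_unet(tiny_network_config())
  ds <- tiny_training_set(3)
  cfgT <- train_config(batch_size = 3, epochs = 1, val_fraction = 0, seed = 9)
  f1 <- train(net, ds, cfgT)
  f2 <- train(net, ds, cfgT)
  expect_identical(f1$history$loss[1], f2$history$loss[1])
})

test_that("the best-so-far training loss decreases over epochs", {
  net <- build_aim_unet(tiny_network_config())
  ds <- tiny_training_set(3)
  fit <- train(net, ds, train_config(batch_size = 3, epochs = 8,
                                     val_fraction = 0, seed = 2))
  running_min <- cummin(fit$history$loss)
  expect_lt(running_min[length(running_min)], running_min[1])
  expect_true(all(fit$history$loss >= 0))
  metrics <- as.matrix(fit$history[c("dice", "iou", "recall", "precision")])
  expect_true(all(metrics >= 0 & metrics <= 1))
})

test_that("early stopping halts a plateaued run before the epoch cap", {
  net <- build_aim_unet(tiny_network_config())
  ds <- tiny_training_set(3)
  # an oversized learning rate saturates the sigmoid and flat-lines the
  # loss, so no further improvement is possible and patience runs out
  fit <- train(net, ds, train_config(batch_size = 3, epochs = 30,
                                     learning_rate = 5,
                                     val_fraction = 0,
                                     early_stopping = TRUE, patience = 3,
                                     seed = 2))
  expect_lt(nrow(fit$history), 30)
})

test_that("reported epoch metrics agree with recomputed predictions", {
  net <- build_aim_unet(tiny_network_config())
  ds <- tiny_training_set(3)
  fit <- train(net, ds, train_config(batch_size = 3, epochs = 2,
                                     val_fraction = 0, seed = 6))
  # recompute dice from the returned weights over the same evaluation set
  dices <- vapply(ds, function(p) {
    pm <- predict_slice(net, fit$weights, p$x)
    dice(binarize(pm), p$y)
  }, numeric(1))
  expect_equal(mean(dices), fit$history$dice[nrow(fit$history)],
               tolerance = 1e-6)
})
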