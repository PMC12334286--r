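test_that("soft dice loss matches hand-computed values", {
  t1 <- matrix(c(1, 0, 1, 0), 2)
  expect_equal(dice_loss(t1, t1), 0)  # perfect binary overlap

  k <- 6
  tgt <- matrix(0, 4, 4); tgt[1:2, 1:3] <- 1
  expect_equal(dice_loss(matrix(0, 4, 4), tgt), 1 - 1 / (k + 1))

  ## p = 0.5 everywhere, half the 2x2 grid is tumor
  expect_equal(dice_loss(matrix(0.5, 2, 2), matrix(c(1, 1, 0, 0), 2),
                         smooth = 1e-9), 0.5, tolerance = 1e-6)
  expect_equal(dice_loss(matrix(0.5, 2, 2), matrix(c(1, 1, 0, 0), 2),
                         smooth = 1), 1 - 3 / 5)

  set.seed(10)
  for (i in 1:20) {
    p <- matrix(runif(36), 6); o <- random_binary_mask(6, 6)
    l <- dice_loss(p, o)
    expect_gte(l, 0); expect_lte(l, 1)
    ## exact complement of the smoothed soft DSC
    expect_equal(l, 1 - (2 * sum(p * o) + 1) / (sum(p) + sum(o) + 1))
  }
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "identical")
})

test_that("training configuration enforces the protocol invariants", {
  cfg <- train_config()
  expect_equal(cfg$epochs, 150L)
  expect_equal(cfg$batch_size, 40L)
  expect_equal(cfg$learning_rate, 0.00025)
  expect_equal(cfg$early_stop_patience, 15L)
  expect_equal(cfg$monitor, "val_accuracy")
  expect_error(train_config(early_stop_patience = 200, epochs = 150),
               "early_stop_patience")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(optimizer = "sgd"), "optimizer")
})

test_that("early stopping fires at patience + 1 on a flat monitor", {
  samples <- tiny_phantoms(4, size = 16, seed = 20)
  ## classic U-Net: no batch normalization, so a vanishing learning rate
  ## makes the validation monitor exactly flat after epoch 1
  netw <- build_unet(model_config("unet", input_height = 16,
                                  input_width = 16,
                                  width_multiplier = 0.0625, seed = 5))
  cfg <- train_config(epochs = 12, batch_size = 8, learning_rate = 1e-20,
                      early_stop_patience = 3, monitor = "val_accuracy",
                      seed = 2)
  res <- train(netw, samples, samples, cfg)
  expect_equal(res$stopped_epoch, 4)  # patience + 1
  expect_equal(res$best_epoch, 1)
  expect_lte(nrow(res$history), 12)
})

test_that("a tiny network learns tiny phantoms (loss decreases, dice rises)", {
  samples <- tiny_phantoms(6, size = 16, seed = 22)
  netw <- build_proposed(model_config("proposed", input_height = 16,
                                      input_width = 16,
                                      width_multiplier = 0.0625,
                                      dropout_rate = 0, seed = 6))
  cfg <- train_config(epochs = 25, batch_size = 8, learning_rate = 0.002,
                      early_stop_patience = 25, monitor = "val_dice",
                      seed = 3)
  res <- train(netw, samples, samples, cfg)
  h <- res$history
  expect_equal(res$steps, 25)
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_gte(max(h$dice), h$dice[1])
  ## the restored state is the best monitored epoch
  expect_equal(res$best_epoch, which.max(h$val_dice)[1])
  expect_error(train(netw, list(), samples, cfg), "non-empty")
})
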