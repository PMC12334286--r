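test_that("model configurations validate their fields", {
  expect_error(model_config("unet", input_height = 100), "divisible by 16")
  expect_error(model_config("unet", dropout_rate = 1), "dropout_rate")
  expect_error(model_config("proposed",
                            decoder_widths = c(64, 64, 32, 16)),
               "decoder_widths")
  expect_error(build_unet(model_config("proposed", input_height = 64,
                                       input_width = 64)),
               "architecture")
  expect_error(cbam_config(spatial_kernel = 4), "spatial_kernel")
})

test_that("every architecture produces sigmoid probabilities at input size", {
  set.seed(1)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  for (arch in c("unet", "vgg19_unet", "proposed")) {
    netw <- build_network(model_config(arch, input_height = 64,
                                       input_width = 64,
                                       width_multiplier = 0.125, seed = 2))
    p <- predict_prob(netw, img)
    expect_identical(dim(p), c(64L, 64L))
    expect_true(all(is.finite(p)))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("predict_mask thresholds the probability map", {
  netw <- build_proposed(model_config("proposed", input_height = 32,
                                      input_width = 32,
                                      width_multiplier = 0.0625, seed = 4))
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  m_all <- predict_mask(netw, img, threshold = 0)
  expect_true(all(m_all == 1))
  m_none <- predict_mask(netw, img, threshold = 1.01)
  expect_true(all(m_none == 0))
  p <- predict_prob(netw, img)
  expect_identical(predict_mask(netw, img, 0.5), (p >= 0.5) * 1)
  expect_error(predict_prob(netw, array(0, c(16, 16, 3))), "shape")
})

test_that("the parameter census partitions the full parameter set", {
  netw <- build_vgg19_unet(model_config("vgg19_unet", input_height = 32,
                                        input_width = 32,
                                        width_multiplier = 0.125, seed = 1))
  cen <- count_parameters(netw)
  total <- sum(vapply(netw$net$params, function(p) length(p$value),
                      numeric(1)))
  expect_equal(cen$trainable + cen$non_trainable, total)
  expect_gte(cen$flops, 0)

  ## frozen encoder: every encoder weight becomes non-trainable
  frozen <- build_vgg19_unet(model_config("vgg19_unet", input_height = 32,
                                          input_width = 32,
                                          width_multiplier = 0.125,
                                          encoder_trainable = FALSE,
                                          seed = 1))
  cen_f <- count_parameters(frozen)
  enc_params <- sum(vapply(
    frozen$net$params[grepl("^enc\\.", names(frozen$net$params))],
    function(p) length(p$value), numeric(1)))
  expect_equal(cen_f$non_trainable, cen$non_trainable + enc_params)
  expect_equal(cen_f$trainable + enc_params, cen$trainable)
})

test_that("a single 3x3 convolution 3->64 with bias has 1792 parameters", {
  net <- tumorseg:::new_collector()
  tumorseg:::layer_conv(net, "c", 3L, 3L, 64L, 8L, 8L)
  expect_equal(sum(vapply(net$params, function(p) length(p$value),
                          numeric(1))), 1792)
})

test_that("conv-layer parameters scale quadratically with the width multiplier", {
  full <- count_parameters(build_unet(model_config("unet", input_height = 32,
                                                   input_width = 32,
                                                   seed = 1)))
  eighth <- count_parameters(build_unet(model_config("unet",
                                                     input_height = 32,
                                                     input_width = 32,
                                                     width_multiplier = 0.125,
                                                     seed = 1)))
  ratio <- full$trainable / eighth$trainable
  ## conv-dominated layers shrink by about (1/8)^2 = 64; the input and head
  ## layers do not, so the overall ratio sits slightly below 64
  expect_gt(ratio, 45)
  expect_lte(ratio, 64)
})

test_that("the VGG19 encoder stack contributes exactly 20,024,384 weights", {
  netw <- build_vgg19_unet(model_config("vgg19_unet"))
  enc <- netw$net$params[grepl("^enc\\.", names(netw$net$params))]
  expect_equal(sum(vapply(enc, function(p) length(p$value), numeric(1))),
               20024384)
  ## five tap-off points, one per VGG19 block
  expect_equal(sum(grepl("^enc\\.b[1-5]\\.conv1\\.w$",
                         names(netw$net$params))), 5)

  ## lightness ordering: proposed < VGG19-U-Net < the 41.0e6 of the
  ## residual variant
  prop <- count_parameters(build_proposed(model_config("proposed")))
  vgg <- count_parameters(netw)
  expect_lt(prop$trainable, vgg$trainable)
  expect_lt(vgg$trainable, 41.0e6)
})

test_that("networks round-trip through save_network/load_network", {
  dir <- withr::local_tempdir()
  netw <- build_proposed(model_config("proposed", input_height = 16,
                                      input_width = 16,
                                      width_multiplier = 0.0625, seed = 3))
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p1 <- predict_prob(netw, img)
  save_network(netw, file.path(dir, "net.rds"))
  p2 <- predict_prob(load_network(file.path(dir, "net.rds")), img)
  expect_equal(p1, p2)
})
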