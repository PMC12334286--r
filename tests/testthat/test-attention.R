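test_that("channel attention is 0.5 on zero input and bounded in (0,1)", {
  cfg <- cbam_config()
  w <- channel_attention(array(0, c(8, 8, 4)), cfg)
  expect_length(w, 4)
  expect_equal(w, rep(0.5, 4))

  set.seed(1)
  for (cc in c(1, 3, 16)) {
    f <- array(rnorm(10 * 12 * cc), c(10, 12, cc))
    w <- channel_attention(f, cfg, seed = 2)
    expect_length(w, cc)
    expect_true(all(w > 0 & w < 1))
  }
})

test_that("channel attention is invariant to spatial upscaling of constant maps", {
  cfg <- cbam_config()
  base <- array(rep(c(0.2, -1, 3), each = 6 * 6), c(6, 6, 3))
  big <- array(rep(c(0.2, -1, 3), each = 12 * 12), c(12, 12, 3))
  expect_equal(channel_attention(base, cfg, seed = 5),
               channel_attention(big, cfg, seed = 5))
})

test_that("spatial attention maps have the input's spatial shape", {
  cfg <- cbam_config()
  m <- spatial_attention(array(0, c(9, 7, 3)), cfg)
  expect_identical(dim(m), c(9L, 7L))
  expect_equal(as.numeric(m), rep(0.5, 63))

  set.seed(2)
  f <- array(rnorm(12 * 12 * 5), c(12, 12, 5))
  m <- spatial_attention(f, cfg, seed = 3)
  expect_true(all(m > 0 & m < 1))
})

test_that("a standard 7x7 two-channel spatial convolution has 99 parameters", {
  cfg_std <- cbam_config(use_separable_convs = FALSE)
  cc <- 16L
  cr <- cc %/% cfg_std$reduction_ratio
  mlp_params <- 2 * cc * cr + cr + cc
  expect_equal(cbam_census(cc, cfg_std)$trainable - mlp_params,
               7 * 7 * 2 + 1)
  expect_equal(cbam_census(cc, cfg_std)$non_trainable, 0)
})

test_that("CBAM output is the input gated by its two attention maps", {
  cfg <- cbam_config()
  set.seed(3)
  f <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  w <- tumorseg:::init_cbam_weights(4, cfg, seed = 9)
  cw <- channel_attention(f, cfg, weights = w)
  refined <- sweep(f, 3, cw, "*")
  sm <- spatial_attention(refined, cfg, weights = w)
  manual <- refined * array(rep(sm, 4), dim(f))
  expect_equal(cbam(f, cfg, weights = w), manual)

  z <- cbam(array(0, c(8, 8, 4)), cfg, seed = 1)
  expect_true(all(z == 0))
  expect_identical(dim(cbam(array(rnorm(32 * 32 * 6), c(32, 32, 6)), cfg)),
                   c(32L, 32L, 6L))
})

test_that("separable unit parameter counts match the closed form", {
  ## census of a built unit vs the layer-by-layer formula
  expect_equal(separable_unit_census(64, 128),
               list(trainable = 9 * 64 + 64 + 64 * 128 + 128 + 2 * 128,
                    non_trainable = 2 * 128))
  set.seed(6)
  for (k in 1:20) {
    cin <- sample(1:96, 1); cout <- sample(1:96, 1)
    cen <- separable_unit_census(cin, cout)
    expect_equal(cen$trainable,
                 9 * cin + cin + cin * cout + cout + 2 * cout)
    expect_equal(cen$non_trainable, 2 * cout)
  }
})

test_that("separable units are far lighter than standard convolutions", {
  cc <- 256
  sep <- separable_unit_census(cc, cc)$trainable
  std <- 9 * cc^2 + cc
  expect_lt(sep, std / 5)
})

test_that("separable_conv_unit produces activated same-size feature maps", {
  set.seed(7)
  f <- array(rnorm(10 * 14 * 3), c(10, 14, 3))
  out <- separable_conv_unit(f, filters = 5, seed = 2)
  expect_identical(dim(out), c(10L, 14L, 5L))
  expect_true(all(out >= 0))  # ReLU
})
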