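## Layer constructors.
##
## A network under construction is an environment (the "collector") holding
## the parameter list and a per-layer census (name, kind, output shape,
## trainable / non-trainable parameter counts, forward-pass FLOPs). Each
## constructor registers its parameters and returns a forward closure mapping
## an autodiff node to an autodiff node.
##
## FLOP convention: multiply and add are counted separately (2 ops per
## multiply-accumulate) for convolutions and dense layers, one forward pass;
## biases, batch normalization, poolings and activations are counted as one
## op per output element. The convention is documented, not tuned to any
## published figure.

new_collector <- function() {
  net <- new.env(parent = emptyenv())
  net$params <- list()
  net$layers <- list()
  net
}

add_param <- function(net, name, nrow_, ncol_ = NULL, init = "he",
                      fan_in = NULL, trainable = TRUE) {
  value <- switch(init,
    he = matrix(stats::rnorm(nrow_ * ncol_, sd = sqrt(2 / fan_in)),
                nrow_, ncol_),
    zero = if (is.null(ncol_)) numeric(nrow_) else matrix(0, nrow_, ncol_),
    one = if (is.null(ncol_)) rep(1, nrow_) else matrix(1, nrow_, ncol_),
    stop("unknown init ", init)
  )
  p <- ag_param(value, name, trainable)
  net$params[[name]] <- p
  p
}

add_layer_record <- function(net, name, kind, out_shape, n_train, n_fixed,
                             flops) {
  net$layers[[length(net$layers) + 1L]] <- list(
    name = name, kind = kind,
    out_shape = paste(out_shape, collapse = "x"),
    trainable = n_train, non_trainable = n_fixed, flops = flops)
}

## standard k x k convolution (+ optional activation)
layer_conv <- function(net, name, k, cin, cout, h, w, trainable = TRUE,
                       activation = "relu") {
  W <- add_param(net, paste0(name, ".w"), k * k * cin, cout,
                 fan_in = k * k * cin, trainable = trainable)
  b <- add_param(net, paste0(name, ".b"), cout, 1L, init = "zero",
                 trainable = trainable)
  np <- k * k * cin * cout + cout
  add_layer_record(net, name, sprintf("conv%dx%d", k, k), c(h, w, cout),
                   if (trainable) np else 0L, if (trainable) 0L else np,
                   2 * k * k * cin * cout * h * w + h * w * cout)
  act <- activation
  function(x, training = FALSE) {
    y <- ag_conv2d(x, W, b, k)
    switch(act, relu = ag_relu(y), sigmoid = ag_sigmoid(y), linear = y)
  }
}

## batch normalization layer
layer_bn <- function(net, name, cc, h, w, trainable = TRUE) {
  gamma <- add_param(net, paste0(name, ".gamma"), cc, init = "one",
                     trainable = trainable)
  beta <- add_param(net, paste0(name, ".beta"), cc, init = "zero",
                    trainable = trainable)
  rmean <- add_param(net, paste0(name, ".moving_mean"), cc, init = "zero",
                     trainable = FALSE)
  rvar <- add_param(net, paste0(name, ".moving_var"), cc, init = "one",
                    trainable = FALSE)
  add_layer_record(net, name, "batchnorm", c(h, w, cc),
                   if (trainable) 2L * cc else 0L,
                   if (trainable) 2L * cc else 4L * cc,
                   2 * h * w * cc)
  function(x, training = FALSE) {
    ag_batchnorm(x, gamma, beta, rmean, rvar, training = training)
  }
}

## depthwise separable convolution unit: depthwise kxk (bias) + pointwise
## 1x1 (bias) + batch normalization + ReLU
layer_sepconv_unit <- function(net, name, k, cin, cout, h, w,
                               trainable = TRUE, activation = "relu") {
  dw <- add_param(net, paste0(name, ".dw"), k * k, cin, fan_in = k * k,
                  trainable = trainable)
  dwb <- add_param(net, paste0(name, ".dwb"), cin, 1L, init = "zero",
                   trainable = trainable)
  pw <- add_param(net, paste0(name, ".pw"), cin, cout, fan_in = cin,
                  trainable = trainable)
  pwb <- add_param(net, paste0(name, ".pwb"), cout, 1L, init = "zero",
                   trainable = trainable)
  np <- k * k * cin + cin + cin * cout + cout
  add_layer_record(net, name, sprintf("sepconv%dx%d", k, k), c(h, w, cout),
                   if (trainable) np else 0L, if (trainable) 0L else np,
                   2 * (k * k * cin + cin * cout) * h * w + 2 * h * w * cout)
  bn <- layer_bn(net, paste0(name, ".bn"), cout, h, w, trainable = trainable)
  act <- activation
  function(x, training = FALSE) {
    y <- ag_depthwise2d(x, dw, dwb, k)
    y <- ag_pointwise(y, pw, pwb)
    y <- bn(y, training)
    switch(act, relu = ag_relu(y), sigmoid = ag_sigmoid(y), linear = y)
  }
}

## standard 2x2 stride-2 transposed convolution
layer_convtrans <- function(net, name, cin, cout, h, w, trainable = TRUE) {
  W <- add_param(net, paste0(name, ".w"), 4L * cin, cout, fan_in = cin,
                 trainable = trainable)
  b <- add_param(net, paste0(name, ".b"), cout, 1L, init = "zero",
                 trainable = trainable)
  np <- 4 * cin * cout + cout
  add_layer_record(net, name, "convtrans2x2", c(2 * h, 2 * w, cout),
                   if (trainable) np else 0L, if (trainable) 0L else np,
                   2 * cin * cout * (2 * h) * (2 * w) + (2 * h) * (2 * w) * cout)
  function(x, training = FALSE) ag_convtrans2(x, W, b)
}

## depthwise-separable 2x2 stride-2 transposed convolution:
## depthwise 2x2 transposed (bias) + pointwise 1x1 (bias)
layer_septrans <- function(net, name, cin, cout, h, w, trainable = TRUE) {
  dw <- add_param(net, paste0(name, ".dw"), 4L, cin, fan_in = 1,
                  trainable = trainable)
  dwb <- add_param(net, paste0(name, ".dwb"), cin, 1L, init = "zero",
                   trainable = trainable)
  pw <- add_param(net, paste0(name, ".pw"), cin, cout, fan_in = cin,
                  trainable = trainable)
  pwb <- add_param(net, paste0(name, ".pwb"), cout, 1L, init = "zero",
                   trainable = trainable)
  np <- 4 * cin + cin + cin * cout + cout
  add_layer_record(net, name, "septrans2x2", c(2 * h, 2 * w, cout),
                   if (trainable) np else 0L, if (trainable) 0L else np,
                   2 * (cin + cin * cout) * (2 * h) * (2 * w))
  function(x, training = FALSE) {
    y <- ag_dwtrans2(x, dw, dwb)
    ag_pointwise(y, pw, pwb)
  }
}

layer_maxpool <- function(net, name, cc, h, w) {
  add_layer_record(net, name, "maxpool2x2", c(h %/% 2L, w %/% 2L, cc),
                   0L, 0L, h * w * cc)
  function(x, training = FALSE) ag_maxpool2(x)
}

layer_dropout <- function(net, name, rate, cc, h, w) {
  add_layer_record(net, name, sprintf("dropout(%.2g)", rate), c(h, w, cc),
                   0L, 0L, 0)
  function(x, training = FALSE) ag_dropout(x, rate, training)
}

## CBAM: channel attention (shared two-layer bottleneck over average- and
## max-pooled descriptors) followed by spatial attention (channel mean/max
## maps -> k x k convolution -> sigmoid). No batch normalization inside.
layer_cbam <- function(net, name, cc, h, w, config, trainable = TRUE) {
  cr <- max(1L, cc %/% config$reduction_ratio)
  w1 <- add_param(net, paste0(name, ".mlp1"), cc, cr, fan_in = cc,
                  trainable = trainable)
  b1 <- add_param(net, paste0(name, ".mlp1b"), cr, 1L, init = "zero",
                  trainable = trainable)
  w2 <- add_param(net, paste0(name, ".mlp2"), cr, cc, fan_in = cr,
                  trainable = trainable)
  b2 <- add_param(net, paste0(name, ".mlp2b"), cc, 1L, init = "zero",
                  trainable = trainable)
  k <- config$spatial_kernel
  if (config$use_separable_convs) {
    sdw <- add_param(net, paste0(name, ".sdw"), k * k, 2L, fan_in = k * k,
                     trainable = trainable)
    sdwb <- add_param(net, paste0(name, ".sdwb"), 2L, 1L, init = "zero",
                      trainable = trainable)
    spw <- add_param(net, paste0(name, ".spw"), 2L, 1L, fan_in = 2,
                     trainable = trainable)
    spwb <- add_param(net, paste0(name, ".spwb"), 1L, 1L, init = "zero",
                      trainable = trainable)
    np_sp <- 2 * k * k + 2 + 2 + 1
  } else {
    sw <- add_param(net, paste0(name, ".sconv"), k * k * 2L, 1L,
                    fan_in = k * k * 2, trainable = trainable)
    sb <- add_param(net, paste0(name, ".sconvb"), 1L, 1L, init = "zero",
                    trainable = trainable)
    np_sp <- k * k * 2 + 1
  }
  np <- cc * cr * 2 + cr + cc + np_sp
  add_layer_record(net, name, "cbam", c(h, w, cc),
                   if (trainable) np else 0L, if (trainable) 0L else np,
                   2 * (2 * cc * cr * 2) + 2 * k * k * 2 * h * w +
                     4 * h * w * cc)
  sep <- config$use_separable_convs
  mlp <- function(d) ag_dense(ag_relu(ag_dense(d, w1, b1)), w2, b2)
  function(x, training = FALSE) {
    cw <- ag_sigmoid(ag_add(mlp(ag_global_avgpool(x)),
                            mlp(ag_global_maxpool(x))))
    y <- ag_scale_channels(x, cw)
    pooled <- ag_concat(ag_channel_mean(y), ag_channel_max(y))
    sm <- if (sep) {
      ag_pointwise(ag_depthwise2d(pooled, sdw, sdwb, k), spw, spwb)
    } else {
      ag_conv2d(pooled, sw, sb, k)
    }
    ag_scale_spatial(y, ag_sigmoid(sm))
  }
}
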