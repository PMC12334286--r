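## Functional interface to the attention blocks.
##
## These wrappers apply a CBAM (or one of its halves) to a single (h,w,C)
## feature array with freshly initialized weights, which is how the blocks
## are unit-tested and inspected; inside a network the same computation runs
## through layer_cbam() with learned weights. Biases are zero-initialized,
## so an all-zero feature map always produces sigmoid(0) = 0.5 attention
## everywhere, for any weight draw.

init_cbam_weights <- function(channels, config, seed = 0L) {
  cr <- max(1L, channels %/% config$reduction_ratio)
  k <- config$spatial_kernel
  with_seed(seed, list(
    w1 = matrix(stats::rnorm(channels * cr, sd = sqrt(2 / channels)),
                channels, cr),
    b1 = matrix(0, cr, 1L),
    w2 = matrix(stats::rnorm(cr * channels, sd = sqrt(2 / cr)), cr, channels),
    b2 = matrix(0, channels, 1L),
    sdw = matrix(stats::rnorm(k * k * 2, sd = sqrt(2 / (k * k))), k * k, 2L),
    sdwb = matrix(0, 2L, 1L),
    spw = matrix(stats::rnorm(2, sd = 1), 2L, 1L),
    spwb = matrix(0, 1L, 1L),
    sconv = matrix(stats::rnorm(k * k * 2, sd = sqrt(2 / (k * k * 2))),
                   k * k * 2L, 1L),
    sconvb = matrix(0, 1L, 1L)))
}

features_to_node <- function(features) {
  d <- dim(features)
  stopifnot(length(d) == 3L)
  m <- features
  dim(m) <- c(d[1] * d[2], d[3])
  ag_input(with_sp(m, c(1L, d[1], d[2])))
}

#' Channel attention weights of a feature map
#'
#' Average- and max-pooled channel descriptors pass through a shared
#' two-layer bottleneck (reduction ratio `config$reduction_ratio`); the
#' summed outputs are squashed by a sigmoid, giving one weight per channel
#' strictly inside (0,1).
#'
#' @param features (h,w,C) numeric array
#' @param config a [cbam_config()]
#' @param weights optional weight list from `init_cbam_weights`; freshly
#'   initialized from `seed` when omitted
#' @param seed weight-initialization seed
#' @return numeric vector of C channel weights in (0,1)
#' @export
#' @examples
#' channel_attention(array(0, c(8, 8, 4)), cbam_config())  # all 0.5
channel_attention <- function(features, config = cbam_config(),
                              weights = NULL, seed = 0L) {
  d <- dim(features)
  if (is.null(weights)) weights <- init_cbam_weights(d[3], config, seed)
  ag_no_grad({
    x <- features_to_node(features)
    mlp <- function(dsc) {
      ag_dense(ag_relu(ag_dense(dsc, ag_input(weights$w1),
                                ag_input(weights$b1))),
               ag_input(weights$w2), ag_input(weights$b2))
    }
    cw <- ag_sigmoid(ag_add(mlp(ag_global_avgpool(x)),
                            mlp(ag_global_maxpool(x))))
    as.numeric(cw$value)
  })
}

#' Spatial attention map of a feature map
#'
#' Per-pixel mean and max over channels form a 2-channel map that is
#' convolved with a `spatial_kernel` filter (depthwise-separable when
#' `config$use_separable_convs`) and squashed by a sigmoid.
#'
#' @inheritParams channel_attention
#' @return (h,w) matrix of weights in (0,1)
#' @export
spatial_attention <- function(features, config = cbam_config(),
                              weights = NULL, seed = 0L) {
  d <- dim(features)
  if (is.null(weights)) weights <- init_cbam_weights(d[3], config, seed)
  k <- config$spatial_kernel
  ag_no_grad({
    x <- features_to_node(features)
    pooled <- ag_concat(ag_channel_mean(x), ag_channel_max(x))
    sm <- if (config$use_separable_convs) {
      ag_pointwise(ag_depthwise2d(pooled, ag_input(weights$sdw),
                                  ag_input(weights$sdwb), k),
                   ag_input(weights$spw), ag_input(weights$spwb))
    } else {
      ag_conv2d(pooled, ag_input(weights$sconv), ag_input(weights$sconvb), k)
    }
    matrix(ag_sigmoid(sm)$value, d[1], d[2])
  })
}

#' Apply a CBAM block to a feature map
#'
#' Sequential refinement: the feature map is first rescaled per channel by
#' the channel-attention weights, then per pixel by the spatial-attention
#' map computed from the channel-refined features.
#'
#' @inheritParams channel_attention
#' @return (h,w,C) array, `features * channel_weights * spatial_map`
#' @export
cbam <- function(features, config = cbam_config(), weights = NULL,
                 seed = 0L) {
  d <- dim(features)
  if (is.null(weights)) weights <- init_cbam_weights(d[3], config, seed)
  cw <- channel_attention(features, config, weights)
  refined <- sweep(features, 3L, cw, "*")
  sm <- spatial_attention(refined, config, weights)
  refined * array(rep(sm, d[3]), d)
}

#' Apply one depthwise separable convolution unit to a feature map
#'
#' Depthwise `kernel x kernel` convolution (with bias), pointwise 1x1
#' convolution to `filters` channels (with bias), batch normalization
#' (batch statistics) and ReLU, with same-padding throughout.
#'
#' @param features (h,w,C) numeric array
#' @param filters number of output channels
#' @param kernel odd kernel size
#' @param seed weight-initialization seed
#' @return (h,w,filters) array
#' @export
separable_conv_unit <- function(features, filters, kernel = 3L, seed = 0L) {
  d <- dim(features)
  stopifnot(length(d) == 3L, filters >= 1L, kernel %% 2L == 1L)
  with_seed(seed, {
    net <- new_collector()
    unit <- layer_sepconv_unit(net, "unit", kernel, d[3], filters,
                               d[1], d[2])
    out <- ag_no_grad(unit(features_to_node(features), training = TRUE))
    array(out$value, c(d[1], d[2], filters))
  })
}

#' Parameter census of a single separable convolution unit
#'
#' Builds one batch-normalized separable convolution unit and reports the
#' framework's own trainable / non-trainable parameter counts. The closed
#' form is `k^2 Cin + Cin + Cin Cout + Cout + 2 Cout` trainable and
#' `2 Cout` non-trainable (moving statistics).
#'
#' @param c_in,c_out input and output channel counts
#' @param kernel odd kernel size
#' @return list with `trainable` and `non_trainable`
#' @export
#' @examples
#' separable_unit_census(64, 128)  # 9216 trainable, 256 non-trainable
separable_unit_census <- function(c_in, c_out, kernel = 3L) {
  net <- new_collector()
  layer_sepconv_unit(net, "unit", kernel, c_in, c_out, 8L, 8L)
  tr <- 0; fx <- 0
  for (p in net$params) {
    if (p$trainable) tr <- tr + length(p$value) else fx <- fx + length(p$value)
  }
  list(trainable = tr, non_trainable = fx)
}

#' Parameter census of one CBAM block
#' @param channels feature channels entering the block
#' @param config a [cbam_config()]
#' @return list with `trainable` and `non_trainable`
#' @export
cbam_census <- function(channels, config = cbam_config()) {
  net <- new_collector()
  layer_cbam(net, "cbam", channels, 8L, 8L, config)
  tr <- 0; fx <- 0
  for (p in net$params) {
    if (p$trainable) tr <- tr + length(p$value) else fx <- fx + length(p$value)
  }
  list(trainable = tr, non_trainable = fx)
}
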