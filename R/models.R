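#' Attention-block hyperparameters
#'
#' Configuration of the convolutional block attention module (CBAM) used in
#' the decoder of the proposed network: the channel-attention bottleneck
#' reduction ratio, the spatial-attention kernel size, and whether the
#' spatial convolution is depthwise-separable.
#'
#' @param reduction_ratio positive integer; channel-attention bottleneck
#'   width is `floor(C / reduction_ratio)`, floored at 1.
#' @param spatial_kernel odd positive integer, kernel size (pixels) of the
#'   spatial-attention convolution.
#' @param use_separable_convs logical; use a depthwise-separable convolution
#'   for the spatial-attention map.
#' @return object of class `cbam_config`
#' @export
#' @examples
#' cbam_config(reduction_ratio = 8, spatial_kernel = 7)
cbam_config <- function(reduction_ratio = 8L, spatial_kernel = 7L,
                        use_separable_convs = TRUE) {
  check_number(reduction_ratio, "reduction_ratio", lower = 1, integer = TRUE)
  check_number(spatial_kernel, "spatial_kernel", lower = 1, integer = TRUE)
  if (spatial_kernel %% 2L == 0L) {
    abort_field("spatial_kernel", "must be odd")
  }
  structure(list(reduction_ratio = as.integer(reduction_ratio),
                 spatial_kernel = as.integer(spatial_kernel),
                 use_separable_convs = isTRUE(use_separable_convs)),
            class = "cbam_config")
}

#' Segmentation network configuration
#'
#' @param architecture one of `"unet"` (classic symmetric U-Net),
#'   `"vgg19_unet"` (VGG19 convolutional encoder with a standard-convolution
#'   decoder), `"proposed"` (VGG19 encoder with a CBAM-refined
#'   depthwise-separable decoder).
#' @param input_height,input_width input resolution in pixels; must be
#'   divisible by 16 (four 2x2 poolings).
#' @param input_channels number of input channels (3 for replicated-RGB MRI
#'   slices).
#' @param decoder_widths strictly decreasing channel counts of the decoder
#'   stages; defaults depend on the architecture (`c(512,256,128,64)` for
#'   `unet`/`vgg19_unet`, `c(256,128,64,32)` for `proposed`).
#' @param convs_per_decoder_stage number of batch-normalized separable
#'   convolution units per decoder stage of the proposed network.
#' @param dropout_rate dropout fraction applied after each encoder block of
#'   the proposed network.
#' @param cbam a [cbam_config()].
#' @param encoder_trainable logical; when `FALSE` the encoder weights are
#'   frozen (counted as non-trainable).
#' @param width_multiplier fraction scaling every channel width (floored at
#'   1); values below 1 build small models for desk-scale experiments.
#' @param up_channels width of the depthwise-separable transposed-convolution
#'   carrier path in the proposed decoder (see the methods vignette for why
#'   this path is narrow).
#' @param seed integer used to initialize the weights.
#' @return object of class `model_config`
#' @export
model_config <- function(architecture = c("unet", "vgg19_unet", "proposed"),
                         input_height = 256L, input_width = 256L,
                         input_channels = 3L,
                         decoder_widths = NULL,
                         convs_per_decoder_stage = 3L,
                         dropout_rate = 0.2,
                         cbam = cbam_config(),
                         encoder_trainable = TRUE,
                         width_multiplier = 1,
                         up_channels = 8L,
                         seed = 42L) {
  architecture <- match.arg(architecture)
  check_number(input_height, "input_height", lower = 16, integer = TRUE)
  check_number(input_width, "input_width", lower = 16, integer = TRUE)
  if (input_height %% 16L || input_width %% 16L) {
    abort_field("input_height/input_width", "must be divisible by 16")
  }
  check_number(dropout_rate, "dropout_rate", lower = 0)
  if (dropout_rate >= 1) abort_field("dropout_rate", "must be in [0,1)")
  check_number(width_multiplier, "width_multiplier", lower = 0,
               strict_lower = TRUE)
  check_number(convs_per_decoder_stage, "convs_per_decoder_stage", lower = 1,
               integer = TRUE)
  check_number(up_channels, "up_channels", lower = 1, integer = TRUE)
  if (is.null(decoder_widths)) {
    decoder_widths <- if (architecture == "proposed") {
      c(256L, 128L, 64L, 32L)
    } else {
      c(512L, 256L, 128L, 64L)
    }
  }
  if (length(decoder_widths) != 4L || any(diff(decoder_widths) >= 0)) {
    abort_field("decoder_widths",
                "must be 4 strictly decreasing channel counts")
  }
  if (!inherits(cbam, "cbam_config")) {
    abort_field("cbam", "must be a cbam_config()")
  }
  structure(list(architecture = architecture,
                 input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 input_channels = as.integer(input_channels),
                 decoder_widths = as.integer(decoder_widths),
                 convs_per_decoder_stage = as.integer(convs_per_decoder_stage),
                 dropout_rate = dropout_rate,
                 cbam = cbam,
                 encoder_trainable = isTRUE(encoder_trainable),
                 width_multiplier = width_multiplier,
                 up_channels = as.integer(up_channels),
                 seed = as.integer(seed)),
            class = "model_config")
}

scale_width <- function(cc, wm) pmax(1L, as.integer(round(cc * wm)))

## VGG19 convolutional stack: 5 blocks of (2,2,4,4,4) 3x3 convolutions at
## widths (64,128,256,512,512), 2x2 max pooling after blocks 1-4. Returns a
## closure yielding the per-block tap nodes (after the optional dropout).
build_vgg19_encoder <- function(net, h, w, cin, wm, dropout_rate = NULL,
                                trainable = TRUE) {
  nconvs <- c(2L, 2L, 4L, 4L, 4L)
  widths <- scale_width(c(64L, 128L, 256L, 512L, 512L), wm)
  blocks <- list()
  ch <- h; cw <- w; cprev <- cin
  for (b in 1:5) {
    convs <- list()
    for (k in seq_len(nconvs[b])) {
      convs[[k]] <- layer_conv(net, sprintf("enc.b%d.conv%d", b, k), 3L,
                               cprev, widths[b], ch, cw,
                               trainable = trainable)
      cprev <- widths[b]
    }
    drop <- if (!is.null(dropout_rate) && dropout_rate > 0) {
      layer_dropout(net, sprintf("enc.b%d.dropout", b), dropout_rate,
                    widths[b], ch, cw)
    } else {
      NULL
    }
    pool <- if (b < 5L) {
      p <- layer_maxpool(net, sprintf("enc.b%d.pool", b), widths[b], ch, cw)
      ch <- ch %/% 2L; cw <- cw %/% 2L
      p
    } else {
      NULL
    }
    blocks[[b]] <- list(convs = convs, drop = drop, pool = pool)
  }
  list(
    widths = widths,
    forward = function(x, training = FALSE) {
      taps <- vector("list", 5L)
      for (b in 1:5) {
        for (cv in blocks[[b]]$convs) x <- cv(x, training)
        if (!is.null(blocks[[b]]$drop)) x <- blocks[[b]]$drop(x, training)
        taps[[b]] <- x
        if (!is.null(blocks[[b]]$pool)) x <- blocks[[b]]$pool(x, training)
      }
      taps
    }
  )
}

new_seg_network <- function(architecture, config, net, forward) {
  structure(list(architecture = architecture, config = config, net = net,
                 forward = forward),
            class = "seg_network")
}

#' Build the classic symmetric U-Net
#'
#' Encoder stages of two 3x3 ReLU convolutions at widths 64/128/256/512 with
#' 2x2 max pooling, a 1024-wide bottleneck, and a mirrored decoder of 2x2
#' transposed convolutions, skip concatenations and two 3x3 convolutions per
#' stage, ending in a 1x1 sigmoid head.
#'
#' @param config a [model_config()] with `architecture = "unet"`
#' @return a `seg_network`
#' @export
#' @examples
#' net <- build_unet(model_config("unet", input_height = 64,
#'                                input_width = 64, width_multiplier = 0.125))
#' count_parameters(net)
build_unet <- function(config = model_config("unet")) {
  stopifnot(inherits(config, "model_config"))
  if (config$architecture != "unet") {
    abort_field("architecture", "expected 'unet'")
  }
  with_seed(config$seed, {
    net <- new_collector()
    wm <- config$width_multiplier
    h <- config$input_height; w <- config$input_width
    widths <- scale_width(c(64L, 128L, 256L, 512L), wm)
    wbot <- scale_width(1024L, wm)
    enc <- list(); ch <- h; cw <- w; cprev <- config$input_channels
    for (s in 1:4) {
      c1 <- layer_conv(net, sprintf("enc.s%d.conv1", s), 3L, cprev,
                       widths[s], ch, cw)
      c2 <- layer_conv(net, sprintf("enc.s%d.conv2", s), 3L, widths[s],
                       widths[s], ch, cw)
      pool <- layer_maxpool(net, sprintf("enc.s%d.pool", s), widths[s],
                            ch, cw)
      enc[[s]] <- list(c1 = c1, c2 = c2, pool = pool)
      cprev <- widths[s]; ch <- ch %/% 2L; cw <- cw %/% 2L
    }
    b1 <- layer_conv(net, "bottleneck.conv1", 3L, cprev, wbot, ch, cw)
    b2 <- layer_conv(net, "bottleneck.conv2", 3L, wbot, wbot, ch, cw)
    dec <- list(); cprev <- wbot
    for (s in 1:4) {
      d <- widths[5L - s]
      up <- layer_convtrans(net, sprintf("dec.s%d.up", s), cprev, d, ch, cw)
      ch <- ch * 2L; cw <- cw * 2L
      c1 <- layer_conv(net, sprintf("dec.s%d.conv1", s), 3L, 2L * d, d,
                       ch, cw)
      c2 <- layer_conv(net, sprintf("dec.s%d.conv2", s), 3L, d, d, ch, cw)
      dec[[s]] <- list(up = up, c1 = c1, c2 = c2)
      cprev <- d
    }
    head <- layer_conv(net, "head", 1L, cprev, 1L, h, w,
                       activation = "sigmoid")
    forward <- function(x, training = FALSE) {
      skips <- vector("list", 4L)
      for (s in 1:4) {
        x <- enc[[s]]$c2(enc[[s]]$c1(x, training), training)
        skips[[s]] <- x
        x <- enc[[s]]$pool(x, training)
      }
      x <- b2(b1(x, training), training)
      for (s in 1:4) {
        x <- dec[[s]]$up(x, training)
        x <- ag_concat(x, skips[[5L - s]])
        x <- dec[[s]]$c2(dec[[s]]$c1(x, training), training)
      }
      head(x, training)
    }
    new_seg_network("unet", config, net, forward)
  })
}

#' Build the VGG19-encoder U-Net
#'
#' The VGG19 convolutional stack is the encoder, with skip tap-offs at the
#' last convolution of blocks 1-4 and block 5 as the bridge. The decoder uses
#' standard 2x2 transposed convolutions and two batch-normalized 3x3
#' convolutions per stage at widths given by `decoder_widths`.
#'
#' @param config a [model_config()] with `architecture = "vgg19_unet"`
#' @return a `seg_network`
#' @export
build_vgg19_unet <- function(config = model_config("vgg19_unet")) {
  stopifnot(inherits(config, "model_config"))
  if (config$architecture != "vgg19_unet") {
    abort_field("architecture", "expected 'vgg19_unet'")
  }
  with_seed(config$seed, {
    net <- new_collector()
    wm <- config$width_multiplier
    h <- config$input_height; w <- config$input_width
    enc <- build_vgg19_encoder(net, h, w, config$input_channels, wm,
                               trainable = config$encoder_trainable)
    dwidths <- scale_width(config$decoder_widths, wm)
    skips <- enc$widths[4:1]
    ch <- h %/% 16L; cw <- w %/% 16L
    cprev <- enc$widths[5]
    dec <- list()
    for (s in 1:4) {
      d <- dwidths[s]
      up <- layer_convtrans(net, sprintf("dec.s%d.up", s), cprev, d, ch, cw)
      ch <- ch * 2L; cw <- cw * 2L
      c1 <- layer_conv(net, sprintf("dec.s%d.conv1", s), 3L, d + skips[s],
                       d, ch, cw, activation = "linear")
      n1 <- layer_bn(net, sprintf("dec.s%d.bn1", s), d, ch, cw)
      c2 <- layer_conv(net, sprintf("dec.s%d.conv2", s), 3L, d, d, ch, cw,
                       activation = "linear")
      n2 <- layer_bn(net, sprintf("dec.s%d.bn2", s), d, ch, cw)
      dec[[s]] <- list(up = up, c1 = c1, n1 = n1, c2 = c2, n2 = n2)
      cprev <- d
    }
    head <- layer_conv(net, "head", 1L, cprev, 1L, h, w,
                       activation = "sigmoid")
    forward <- function(x, training = FALSE) {
      taps <- enc$forward(x, training)
      x <- taps[[5]]
      for (s in 1:4) {
        x <- dec[[s]]$up(x, training)
        x <- ag_concat(x, taps[[5L - s]])
        x <- ag_relu(dec[[s]]$n1(dec[[s]]$c1(x, training), training))
        x <- ag_relu(dec[[s]]$n2(dec[[s]]$c2(x, training), training))
      }
      head(x, training)
    }
    new_seg_network("vgg19_unet", config, net, forward)
  })
}

#' Build the proposed lightweight VGG19 U-Net with CBAM
#'
#' VGG19 encoder (dropout after each block) with a depthwise-separable
#' decoder: each of the four stages upsamples through a depthwise-separable
#' 2x2 transposed convolution into a narrow carrier path (`up_channels`
#' wide), concatenates the encoder skip, fuses with a batch-normalized
#' separable convolution unit down to the stage width, refines the fused map
#' with a CBAM block, and applies further separable units at the stage width
#' (`convs_per_decoder_stage` batch-normalized units in total). A 1x1 sigmoid
#' convolution produces the per-pixel tumor probability map.
#'
#' @param config a [model_config()] with `architecture = "proposed"`
#' @return a `seg_network`
#' @export
#' @examples
#' net <- build_proposed(model_config("proposed", input_height = 64,
#'                                    input_width = 64,
#'                                    width_multiplier = 0.125))
#' count_parameters(net)
build_proposed <- function(config = model_config("proposed")) {
  stopifnot(inherits(config, "model_config"))
  if (config$architecture != "proposed") {
    abort_field("architecture", "expected 'proposed'")
  }
  with_seed(config$seed, {
    net <- new_collector()
    wm <- config$width_multiplier
    h <- config$input_height; w <- config$input_width
    enc <- build_vgg19_encoder(net, h, w, config$input_channels, wm,
                               dropout_rate = config$dropout_rate,
                               trainable = config$encoder_trainable)
    dwidths <- scale_width(config$decoder_widths, wm)
    upw <- scale_width(config$up_channels, wm)
    nunits <- config$convs_per_decoder_stage
    skips <- enc$widths[4:1]
    ch <- h %/% 16L; cw <- w %/% 16L
    cprev <- enc$widths[5]
    dec <- list()
    for (s in 1:4) {
      d <- dwidths[s]
      up <- layer_septrans(net, sprintf("dec.s%d.up", s), cprev, upw, ch, cw)
      ch <- ch * 2L; cw <- cw * 2L
      units <- list(layer_sepconv_unit(net, sprintf("dec.s%d.sep1", s), 3L,
                                       upw + skips[s], d, ch, cw))
      cbam <- layer_cbam(net, sprintf("dec.s%d.cbam", s), d, ch, cw,
                         config$cbam)
      if (nunits > 1L) {
        for (u in 2:nunits) {
          units[[u]] <- layer_sepconv_unit(net, sprintf("dec.s%d.sep%d", s, u),
                                           3L, d, d, ch, cw)
        }
      }
      dec[[s]] <- list(up = up, units = units, cbam = cbam)
      cprev <- d
    }
    head <- layer_conv(net, "head", 1L, cprev, 1L, h, w,
                       activation = "sigmoid")
    forward <- function(x, training = FALSE) {
      taps <- enc$forward(x, training)
      x <- taps[[5]]  # bottleneck: pass-through bridge of block-5 features
      for (s in 1:4) {
        x <- dec[[s]]$up(x, training)
        x <- ag_concat(x, taps[[5L - s]])
        x <- dec[[s]]$units[[1]](x, training)
        x <- dec[[s]]$cbam(x, training)
        for (u in seq_along(dec[[s]]$units)[-1]) {
          x <- dec[[s]]$units[[u]](x, training)
        }
      }
      head(x, training)
    }
    new_seg_network("proposed", config, net, forward)
  })
}

#' Build a segmentation network from a configuration
#' @param config a [model_config()]
#' @return a `seg_network`
#' @export
build_network <- function(config) {
  switch(config$architecture,
         unet = build_unet(config),
         vgg19_unet = build_vgg19_unet(config),
         proposed = build_proposed(config))
}

#' Count trainable and non-trainable parameters and forward FLOPs
#'
#' Parameters are partitioned by the trainability flag; batch-normalization
#' moving statistics are non-trainable. FLOPs count multiply and add
#' separately (2 ops per multiply-accumulate) for one forward pass at the
#' configured input resolution.
#'
#' @param network a `seg_network`
#' @return object of class `parameter_census`: list with `trainable`,
#'   `non_trainable` and `flops`
#' @export
count_parameters <- function(network) {
  stopifnot(inherits(network, "seg_network"))
  tr <- 0; fx <- 0
  for (p in network$net$params) {
    if (p$trainable) tr <- tr + length(p$value) else fx <- fx + length(p$value)
  }
  fl <- sum(vapply(network$net$layers, function(l) l$flops, numeric(1)))
  structure(list(trainable = tr, non_trainable = fx, flops = fl),
            class = "parameter_census")
}

#' @export
print.parameter_census <- function(x, ...) {
  cat(sprintf("trainable: %s\nnon-trainable: %s\nforward FLOPs: %.3g\n",
              format(x$trainable, big.mark = ","),
              format(x$non_trainable, big.mark = ","), x$flops))
  invisible(x)
}

#' Layer-by-layer summary table of a network
#' @param object a `seg_network`
#' @param ... unused
#' @return data.frame with one row per layer (name, kind, output shape,
#'   trainable and non-trainable parameter counts, FLOPs)
#' @export
summary.seg_network <- function(object, ...) {
  do.call(rbind, lapply(object$net$layers, function(l) {
    data.frame(name = l$name, kind = l$kind, output = l$out_shape,
               trainable = l$trainable, non_trainable = l$non_trainable,
               flops = l$flops)
  }))
}

#' @export
print.seg_network <- function(x, ...) {
  cen <- count_parameters(x)
  cat(sprintf("<seg_network: %s, input %dx%dx%d, width multiplier %g>\n",
              x$architecture, x$config$input_height, x$config$input_width,
              x$config$input_channels, x$config$width_multiplier))
  print(cen)
  invisible(x)
}

## Convert one (h,w,c) array or a list of them into the internal
## (n*h*w, C) feature matrix (rows ordered sample-fastest).
as_feature_matrix <- function(images) {
  if (!is.list(images)) images <- list(images)
  d <- dim(images[[1]])
  if (length(d) == 2L) d <- c(d, 1L)
  n <- length(images)
  arr <- array(0, c(n, d[1], d[2], d[3]))
  for (s in seq_len(n)) {
    img <- images[[s]]
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    arr[s, , , ] <- img
  }
  dim(arr) <- c(n * d[1] * d[2], d[3])
  with_sp(arr, c(n, d[1], d[2]))
}

## Inverse: (n*h*w, 1) matrix column -> list of (h,w) matrices
prob_maps_from_matrix <- function(m, sp) {
  n <- sp[1]; h <- sp[2]; w <- sp[3]
  lapply(seq_len(n), function(s) {
    matrix(m[seq.int(s, by = n, length.out = h * w), 1L], h, w)
  })
}

#' Predict per-pixel tumor probabilities
#'
#' @param network a `seg_network`
#' @param images one (h,w,C) array, one `mri_sample`, or a list of either
#' @return a list of (h,w) probability matrices (a single matrix if one
#'   image was given)
#' @export
predict_prob <- function(network, images) {
  single <- !is.list(images) || inherits(images, "mri_sample")
  if (single) images <- list(images)
  imgs <- lapply(images, function(x) {
    if (inherits(x, "mri_sample")) x$image else x
  })
  d <- dim(imgs[[1]])
  if (d[1] != network$config$input_height ||
      d[2] != network$config$input_width ||
      (length(d) > 2L && d[3] != network$config$input_channels)) {
    stop(sprintf("input shape %s does not match network input %dx%dx%d",
                 paste(d, collapse = "x"), network$config$input_height,
                 network$config$input_width, network$config$input_channels),
         call. = FALSE)
  }
  x <- as_feature_matrix(imgs)
  out <- ag_no_grad(network$forward(ag_input(x), training = FALSE))
  maps <- prob_maps_from_matrix(out$value, attr(out$value, "sp"))
  if (single) maps[[1]] else maps
}

#' Predict a binary tumor mask
#'
#' Thresholds the sigmoid probability map: a pixel is tumor when its
#' probability is greater than or equal to `threshold`.
#'
#' @inheritParams predict_prob
#' @param threshold probability cutoff (default 0.5)
#' @return binary (h,w) matrix, or list of them
#' @export
predict_mask <- function(network, images, threshold = 0.5) {
  p <- predict_prob(network, images)
  binarize <- function(m) (m >= threshold) * 1
  if (is.list(p)) lapply(p, binarize) else binarize(p)
}
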