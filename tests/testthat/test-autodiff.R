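## Finite-difference validation of the reverse-mode gradients that training
## relies on. Each primitive is checked on small random tensors; a final
## check runs end-to-end through a miniature attention U-Net.

fd_error <- function(make_loss, param, eps = 1e-5, subsample = NULL) {
  loss <- make_loss()
  tumorseg:::ag_backward(loss)
  ana <- as.numeric(param$grad)
  idx <- seq_along(param$value)
  if (!is.null(subsample)) idx <- sample(idx, min(subsample, length(idx)))
  v0 <- param$value
  errs <- vapply(idx, function(i) {
    param$value[i] <- v0[i] + eps
    lp <- as.numeric(make_loss()$value)
    param$value[i] <- v0[i] - eps
    lm <- as.numeric(make_loss()$value)
    param$value[i] <- v0[i]
    num <- (lp - lm) / (2 * eps)
    abs(ana[i] - num) / max(1e-6, abs(num), abs(ana[i]))
  }, numeric(1))
  max(errs)
}

## random linear read-out making any tensor node a scalar loss
readout <- function(y, w) {
  v <- matrix(sum(y$value * w), 1, 1)
  tumorseg:::new_node(v, list(y), function(g) {
    gw <- g[1] * w
    attr(gw, "sp") <- attr(y$value, "sp")
    list(gw)
  })
}

test_that("convolution-family gradients match finite differences", {
  set.seed(1)
  n <- 2; h <- 4; w <- 6; cin <- 3; cout <- 4
  X <- tumorseg:::ag_input(
    tumorseg:::with_sp(matrix(rnorm(n * h * w * cin), n * h * w, cin),
                       c(n, h, w)))
  ro <- matrix(rnorm(n * h * w * cout), n * h * w, cout)
  W <- tumorseg:::ag_param(matrix(rnorm(9 * cin * cout) * 0.3, 9 * cin, cout),
                           "w")
  B <- tumorseg:::ag_param(matrix(rnorm(cout) * 0.1, cout, 1), "b")
  mk <- function() readout(tumorseg:::ag_conv2d(X, W, B, 3L), ro)
  expect_lt(fd_error(mk, W), 1e-6)
  expect_lt(fd_error(mk, B), 1e-6)
  expect_lt(fd_error(mk, X), 1e-6)

  DW <- tumorseg:::ag_param(matrix(rnorm(9 * cin) * 0.3, 9, cin), "dw")
  ro3 <- ro[, 1:cin]
  mkd <- function() readout(tumorseg:::ag_depthwise2d(X, DW, NULL, 3L), ro3)
  expect_lt(fd_error(mkd, DW), 1e-6)
  expect_lt(fd_error(mkd, X), 1e-6)

  TW <- tumorseg:::ag_param(matrix(rnorm(4 * cin * cout) * 0.3, 4 * cin, cout),
                            "tw")
  rot <- matrix(rnorm(4 * n * h * w * cout), 4 * n * h * w, cout)
  mkt <- function() readout(tumorseg:::ag_convtrans2(X, TW, NULL), rot)
  expect_lt(fd_error(mkt, TW), 1e-6)
  expect_lt(fd_error(mkt, X), 1e-6)

  DT <- tumorseg:::ag_param(matrix(rnorm(4 * cin) * 0.3, 4, cin), "dt")
  rod <- matrix(rnorm(4 * n * h * w * cin), 4 * n * h * w, cin)
  mku <- function() readout(tumorseg:::ag_dwtrans2(X, DT, NULL), rod)
  expect_lt(fd_error(mku, DT), 1e-6)
  expect_lt(fd_error(mku, X), 1e-6)
})

test_that("pooling, normalization and attention gradients match finite differences", {
  set.seed(2)
  n <- 2; h <- 4; w <- 6; cin <- 3
  X <- tumorseg:::ag_input(
    tumorseg:::with_sp(matrix(rnorm(n * h * w * cin), n * h * w, cin),
                       c(n, h, w)))
  rop <- matrix(rnorm(n * (h / 2) * (w / 2) * cin), n * (h / 2) * (w / 2), cin)
  expect_lt(fd_error(function() readout(tumorseg:::ag_maxpool2(X), rop), X),
            1e-6)

  G <- tumorseg:::ag_param(rep(1.2, cin), "g")
  Be <- tumorseg:::ag_param(rep(0.1, cin), "be")
  RM <- tumorseg:::ag_param(rep(0, cin), "rm", trainable = FALSE)
  RV <- tumorseg:::ag_param(rep(1, cin), "rv", trainable = FALSE)
  ro3 <- matrix(rnorm(n * h * w * cin), n * h * w, cin)
  mkbn <- function() {
    RM$value <- rep(0, cin); RV$value <- rep(1, cin)
    readout(tumorseg:::ag_batchnorm(X, G, Be, RM, RV, training = TRUE), ro3)
  }
  expect_lt(fd_error(mkbn, X), 1e-5)
  expect_lt(fd_error(mkbn, G), 1e-6)
  expect_lt(fd_error(mkbn, Be), 1e-6)

  CW <- tumorseg:::ag_param(matrix(runif(n * cin), n, cin), "cw")
  mksc <- function() {
    y <- tumorseg:::ag_scale_channels(X, CW)
    pooled <- tumorseg:::ag_concat(tumorseg:::ag_channel_mean(y),
                                   tumorseg:::ag_channel_max(y))
    z <- tumorseg:::ag_scale_spatial(
      y, tumorseg:::ag_channel_mean(tumorseg:::ag_sigmoid(pooled)))
    readout(z, ro3)
  }
  expect_lt(fd_error(mksc, X), 1e-6)
  expect_lt(fd_error(mksc, CW), 1e-6)

  M <- tumorseg:::ag_param(matrix(rnorm(cin * 2) * 0.4, cin, 2), "m")
  mkgp <- function() {
    d <- tumorseg:::ag_dense(tumorseg:::ag_global_avgpool(X), M)
    d2 <- tumorseg:::ag_dense(tumorseg:::ag_global_maxpool(X), M)
    sg <- tumorseg:::ag_sigmoid(tumorseg:::ag_add(d, d2))
    tumorseg:::new_node(matrix(sum(sg$value), 1, 1), list(sg),
                        function(g) list(matrix(g[1], n, 2)))
  }
  expect_lt(fd_error(mkgp, X), 1e-6)
  expect_lt(fd_error(mkgp, M), 1e-6)
})

test_that("the soft dice loss gradient matches finite differences", {
  set.seed(3)
  n <- 2; h <- 4; w <- 4
  P <- tumorseg:::ag_input(
    tumorseg:::with_sp(matrix(rnorm(n * h * w), ncol = 1), c(n, h, w)))
  tgt <- matrix(rbinom(n * h * w, 1, 0.3), ncol = 1)
  mk <- function() {
    tumorseg:::ag_dice_loss(tumorseg:::ag_sigmoid(P), tgt, smooth = 1)
  }
  expect_lt(fd_error(mk, P), 1e-5)
})

test_that("gradients flow end-to-end through a miniature proposed network", {
  set.seed(4)
  cfg <- model_config("proposed", input_height = 16, input_width = 16,
                      width_multiplier = 0.05, dropout_rate = 0, seed = 3)
  netw <- build_proposed(cfg)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  tgt <- matrix(rbinom(256, 1, 0.2), ncol = 1)
  mk <- function() {
    x <- tumorseg:::as_feature_matrix(list(img))
    tumorseg:::ag_dice_loss(netw$forward(tumorseg:::ag_input(x),
                                         training = FALSE), tgt)
  }
  for (pn in c("enc.b1.conv1.w", "dec.s4.sep2.pw", "head.w",
               "dec.s1.up.dw", "dec.s3.sep1.bn.gamma")) {
    expect_lt(fd_error(mk, netw$net$params[[pn]], subsample = 4), 1e-4)
  }
})

test_that("forward evaluation without the tape matches taped evaluation", {
  s <- tiny_phantoms(2, size = 16, seed = 8)
  netw <- build_proposed(model_config("proposed", input_height = 16,
                                      input_width = 16,
                                      width_multiplier = 0.0625, seed = 1))
  x <- tumorseg:::as_feature_matrix(lapply(s, function(z) z$image))
  with_tape <- netw$forward(tumorseg:::ag_input(x), training = FALSE)$value
  no_tape <- tumorseg:::ag_no_grad(
    netw$forward(tumorseg:::ag_input(x), training = FALSE)$value)
  expect_equal(with_tape, no_tape)
})
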