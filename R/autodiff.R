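#' @name autodiff
#' @title Reverse-mode automatic differentiation over feature maps
#'
#' @description
#' A minimal tape-based reverse-mode autodiff engine used to build and train
#' the segmentation networks. A feature map of `n` samples with spatial size
#' `h x w` and `C` channels is stored as an `(n*h*w) x C` numeric matrix whose
#' rows are ordered with the sample index fastest, then rows, then columns
#' (native R array order for `dim = c(n, h, w)`); the spatial shape travels in
#' the `"sp"` attribute. Every operation creates a graph node that carries the
#' forward value and a closure producing the gradients of its parents.
#'
#' Only the operations needed by the U-Net family are provided: dense and
#' convolutional primitives (standard, depthwise, 1x1 pointwise, 2x2
#' transposed and depthwise-transposed), 2x2 max pooling, batch
#' normalization, channel/spatial pooling and rescaling for attention blocks,
#' ReLU/sigmoid, dropout, concatenation, and a soft dice loss.
#' @keywords internal
NULL

.ag <- new.env(parent = emptyenv())
.ag$grad_on <- TRUE
.ag$idc <- 0
.ag$shift_cache <- new.env(parent = emptyenv())

next_id <- function() {
  .ag$idc <- .ag$idc + 1
  sprintf("n%.0f", .ag$idc)
}

ag_grad_enabled <- function() .ag$grad_on

#' Evaluate an expression without recording the autodiff tape
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .ag$grad_on
  .ag$grad_on <- FALSE
  on.exit(.ag$grad_on <- old)
  force(expr)
}

new_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$id <- next_id()
  e$value <- value
  e$grad <- NULL
  if (.ag$grad_on) {
    e$parents <- parents
    e$backfn <- backfn
  } else {
    e$parents <- list()
    e$backfn <- NULL
  }
  class(e) <- "ag_node"
  e
}

#' Create a leaf tensor node
#' @param value numeric matrix (rows = n*h*w, cols = channels)
#' @param sp spatial shape `c(n, h, w)` or `NULL` for plain matrices
#' @keywords internal
ag_input <- function(value, sp = NULL) {
  if (!is.null(sp)) attr(value, "sp") <- as.integer(sp)
  new_node(value)
}

#' Create a parameter node
#'
#' Parameters are leaves that accumulate gradients and are enumerated by the
#' parameter census. Batch-normalization moving statistics are represented as
#' non-trainable parameters so that the census matches the usual trainable /
#' non-trainable partition of deep learning frameworks.
#' @param value numeric matrix or vector of initial values
#' @param name unique parameter name
#' @param trainable logical; updated by the optimizer when `TRUE`
#' @keywords internal
ag_param <- function(value, name, trainable = TRUE) {
  e <- new.env(parent = emptyenv())
  e$id <- next_id()
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$backfn <- NULL
  e$name <- name
  e$trainable <- isTRUE(trainable)
  class(e) <- c("ag_param", "ag_node")
  e
}

ag_sp <- function(x) {
  sp <- attr(x$value, "sp")
  if (is.null(sp)) stop("node has no spatial shape", call. = FALSE)
  sp
}

with_sp <- function(m, sp) {
  attr(m, "sp") <- as.integer(sp)
  m
}

## ---- backward pass ---------------------------------------------------------

#' Run backpropagation from a scalar loss node
#'
#' Fills `$grad` on every reachable node (including parameter leaves) with the
#' derivative of the loss. Gradients of fan-out nodes are accumulated.
#' @param loss node holding a scalar value
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(inherits(loss, "ag_node"), length(loss$value) == 1L)
  ## iterative topological sort (post-order DFS)
  topo <- vector("list", 64L)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- fr$node
    id <- nd$id
    if (fr$stage == 1L) {
      if (!is.null(seen[[id]])) next
      seen[[id]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        pid <- p$id
        if (is.null(seen[[pid]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- nd
    }
  }
  topo <- topo[seq_len(ntopo)]
  for (nd in topo) nd$grad <- NULL
  loss$grad <- matrix(1, 1L, 1L)
  for (k in rev(seq_len(ntopo))) {
    nd <- topo[[k]]
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    pgrads <- nd$backfn(nd$grad)
    for (i in seq_along(nd$parents)) {
      g <- pgrads[[i]]
      if (is.null(g)) next
      p <- nd$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

## ---- shifted-gather machinery ---------------------------------------------

## Index vectors realizing out(i, j) = in(i + di, j + dj) with zero padding,
## cached per (n, h, w, di, dj).
shift_index <- function(n, h, w, di, dj) {
  key <- paste(n, h, w, di, dj, sep = "_")
  hit <- .ag$shift_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- rep(rep.int(seq_len(h), rep.int(n, h)), w)
  j <- rep(seq_len(w), each = n * h)
  s <- rep.int(seq_len(n), h * w)
  ii <- i + di
  jj <- j + dj
  valid <- ii >= 1L & ii <= h & jj >= 1L & jj <= w
  idx <- s + n * ((ii - 1L) + h * (jj - 1L))
  idx[!valid] <- 1L
  out <- list(idx = idx, invalid = which(!valid))
  .ag$shift_cache[[key]] <- out
  out
}

gather_shift <- function(xm, n, h, w, di, dj) {
  si <- shift_index(n, h, w, di, dj)
  y <- xm[si$idx, , drop = FALSE]
  if (length(si$invalid)) y[si$invalid, ] <- 0
  y
}

## adjoint of gather_shift: scatter-add g back through the shift
scatter_shift <- function(g, n, h, w, di, dj) {
  ## out(i,j) = in(i+di, j+dj)  =>  d in(a,b) += g(a-di, b-dj)
  gather_shift(g, n, h, w, -di, -dj)
}

## Patch matrix [gathered shifts, column blocks of size C per offset] for a
## k x k "same" convolution. Offset order: dj outer, di inner, both -p..p.
conv_offsets <- function(k) {
  p <- (k - 1L) %/% 2L
  od <- expand.grid(di = -p:p, dj = -p:p)
  od[order(od$dj, od$di), , drop = FALSE]
}

im2col <- function(xm, n, h, w, k) {
  cc <- ncol(xm)
  off <- conv_offsets(k)
  out <- matrix(0, nrow(xm), k * k * cc)
  for (o in seq_len(nrow(off))) {
    cols <- ((o - 1L) * cc + 1L):(o * cc)
    out[, cols] <- gather_shift(xm, n, h, w, off$di[o], off$dj[o])
  }
  out
}

col2im <- function(g, n, h, w, k, cc) {
  off <- conv_offsets(k)
  acc <- matrix(0, n * h * w, cc)
  for (o in seq_len(nrow(off))) {
    cols <- ((o - 1L) * cc + 1L):(o * cc)
    acc <- acc + scatter_shift(g[, cols, drop = FALSE], n, h, w,
                               off$di[o], off$dj[o])
  }
  acc
}

## ---- elementwise and dense ops --------------------------------------------

ag_relu <- function(x) {
  v <- x$value
  pos <- v > 0
  y <- v * pos
  attr(y, "sp") <- attr(v, "sp")
  new_node(y, list(x), function(g) list(g * pos))
}

ag_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  attr(y, "sp") <- attr(x$value, "sp")
  new_node(y, list(x), function(g) list(g * y * (1 - y)))
}

ag_add <- function(x, y) {
  v <- x$value + y$value
  attr(v, "sp") <- attr(x$value, "sp")
  new_node(v, list(x, y), function(g) list(g, g))
}

ag_matmul <- function(x, w) {
  v <- x$value %*% w$value
  new_node(v, list(x, w), function(g)
    list(g %*% t(w$value), crossprod(x$value, g)))
}

ag_add_bias <- function(x, b) {
  v <- sweep(x$value, 2L, as.numeric(b$value), "+")
  attr(v, "sp") <- attr(x$value, "sp")
  new_node(v, list(x, b), function(g) list(g, colSums(g)))
}

## dense layer y = x %*% W + b for (n, C) descriptor matrices
ag_dense <- function(x, w, b = NULL) {
  y <- ag_matmul(x, w)
  if (!is.null(b)) y <- ag_add_bias(y, b) else y
}

## ---- convolutions ----------------------------------------------------------

#' Standard k x k "same" convolution; weight `(k*k*Cin) x Cout`
#' @keywords internal
ag_conv2d <- function(x, w, b = NULL, k = 3L) {
  sp <- ag_sp(x)
  n <- sp[1]; h <- sp[2]; wd <- sp[3]
  cin <- ncol(x$value)
  patches <- im2col(x$value, n, h, wd, k)
  v <- patches %*% w$value
  if (!is.null(b)) v <- sweep(v, 2L, as.numeric(b$value), "+")
  attr(v, "sp") <- sp
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_node(with_sp(v, sp), parents, function(g) {
    dW <- crossprod(patches, g)
    dP <- g %*% t(w$value)
    dX <- with_sp(col2im(dP, n, h, wd, k, cin), sp)
    if (is.null(b)) list(dX, dW) else list(dX, dW, colSums(g))
  })
}

#' Depthwise k x k "same" convolution; weight `(k*k) x C`
#' @keywords internal
ag_depthwise2d <- function(x, w, b = NULL, k = 3L) {
  sp <- ag_sp(x)
  n <- sp[1]; h <- sp[2]; wd <- sp[3]
  off <- conv_offsets(k)
  v <- matrix(0, nrow(x$value), ncol(x$value))
  for (o in seq_len(nrow(off))) {
    s <- gather_shift(x$value, n, h, wd, off$di[o], off$dj[o])
    v <- v + s * rep(w$value[o, ], each = nrow(s))
  }
  if (!is.null(b)) v <- sweep(v, 2L, as.numeric(b$value), "+")
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_node(with_sp(v, sp), parents, function(g) {
    dW <- matrix(0, nrow(off), ncol(g))
    dX <- matrix(0, nrow(g), ncol(g))
    for (o in seq_len(nrow(off))) {
      s <- gather_shift(x$value, n, h, wd, off$di[o], off$dj[o])
      dW[o, ] <- colSums(s * g)
      dX <- dX + scatter_shift(g * rep(w$value[o, ], each = nrow(g)),
                               n, h, wd, off$di[o], off$dj[o])
    }
    dX <- with_sp(dX, sp)
    if (is.null(b)) list(dX, dW) else list(dX, dW, colSums(g))
  })
}

#' 1x1 pointwise convolution; weight `Cin x Cout`
#' @keywords internal
ag_pointwise <- function(x, w, b = NULL) {
  sp <- ag_sp(x)
  v <- x$value %*% w$value
  if (!is.null(b)) v <- sweep(v, 2L, as.numeric(b$value), "+")
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_node(with_sp(v, sp), parents, function(g) {
    dX <- with_sp(g %*% t(w$value), sp)
    dW <- crossprod(x$value, g)
    if (is.null(b)) list(dX, dW) else list(dX, dW, colSums(g))
  })
}

## Row indices of the four positions of each 2x2 block.
pool_index <- function(n, h, w) {
  key <- paste("pool", n, h, w, sep = "_")
  hit <- .ag$shift_cache[[key]]
  if (!is.null(hit)) return(hit)
  ho <- h %/% 2L; wo <- w %/% 2L
  i <- rep(rep.int(seq_len(ho), rep.int(n, ho)), wo)
  j <- rep(seq_len(wo), each = n * ho)
  s <- rep.int(seq_len(n), ho * wo)
  idx <- vector("list", 4L)
  o <- 0L
  for (b in 0:1) for (a in 0:1) {
    o <- o + 1L
    idx[[o]] <- s + n * ((2L * i - 2L + a) + h * (2L * j - 2L + b))
  }
  .ag$shift_cache[[key]] <- idx
  idx
}

#' 2x2 max pooling, stride 2 (spatial dims must be even)
#' @keywords internal
ag_maxpool2 <- function(x) {
  sp <- ag_sp(x)
  n <- sp[1]; h <- sp[2]; w <- sp[3]
  if (h %% 2L || w %% 2L) {
    stop("max pooling requires even spatial dimensions, got ", h, "x", w,
         call. = FALSE)
  }
  idx <- pool_index(n, h, w)
  g1 <- x$value[idx[[1]], , drop = FALSE]
  g2 <- x$value[idx[[2]], , drop = FALSE]
  g3 <- x$value[idx[[3]], , drop = FALSE]
  g4 <- x$value[idx[[4]], , drop = FALSE]
  v <- pmax(g1, g2, g3, g4)
  spo <- c(n, h %/% 2L, w %/% 2L)
  new_node(with_sp(v, spo), list(x), function(g) {
    dX <- matrix(0, n * h * w, ncol(g))
    claimed <- matrix(FALSE, nrow(g), ncol(g))
    gs <- list(g1, g2, g3, g4)
    for (o in 1:4) {
      m <- (gs[[o]] == v) & !claimed
      claimed <- claimed | m
      dX[idx[[o]], ] <- dX[idx[[o]], ] + g * m
    }
    list(with_sp(dX, sp))
  })
}

## Output row indices per offset for 2x2 stride-2 transposed convolution.
trans_index <- function(n, h, w) {
  key <- paste("trans", n, h, w, sep = "_")
  hit <- .ag$shift_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- rep(rep.int(seq_len(h), rep.int(n, h)), w)
  j <- rep(seq_len(w), each = n * h)
  s <- rep.int(seq_len(n), h * w)
  idx <- vector("list", 4L)
  o <- 0L
  for (b in 0:1) for (a in 0:1) {
    o <- o + 1L
    idx[[o]] <- s + n * ((2L * i - 2L + a) + 2L * h * (2L * j - 2L + b))
  }
  .ag$shift_cache[[key]] <- idx
  idx
}

#' 2x2 stride-2 transposed convolution; weight `(4*Cin) x Cout`
#' @keywords internal
ag_convtrans2 <- function(x, w, b = NULL) {
  sp <- ag_sp(x)
  n <- sp[1]; h <- sp[2]; wd <- sp[3]
  cin <- ncol(x$value)
  cout <- ncol(w$value)
  idx <- trans_index(n, h, wd)
  v <- matrix(0, n * 4L * h * wd, cout)
  for (o in 1:4) {
    rows <- ((o - 1L) * cin + 1L):(o * cin)
    v[idx[[o]], ] <- x$value %*% w$value[rows, , drop = FALSE]
  }
  if (!is.null(b)) v <- sweep(v, 2L, as.numeric(b$value), "+")
  spo <- c(n, 2L * h, 2L * wd)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_node(with_sp(v, spo), parents, function(g) {
    dX <- matrix(0, n * h * wd, cin)
    dW <- matrix(0, 4L * cin, cout)
    for (o in 1:4) {
      rows <- ((o - 1L) * cin + 1L):(o * cin)
      go <- g[idx[[o]], , drop = FALSE]
      dX <- dX + go %*% t(w$value[rows, , drop = FALSE])
      dW[rows, ] <- crossprod(x$value, go)
    }
    dX <- with_sp(dX, sp)
    if (is.null(b)) list(dX, dW) else list(dX, dW, colSums(g))
  })
}

#' Depthwise 2x2 stride-2 transposed convolution; weight `4 x C`
#' @keywords internal
ag_dwtrans2 <- function(x, w, b = NULL) {
  sp <- ag_sp(x)
  n <- sp[1]; h <- sp[2]; wd <- sp[3]
  cc <- ncol(x$value)
  idx <- trans_index(n, h, wd)
  v <- matrix(0, n * 4L * h * wd, cc)
  for (o in 1:4) {
    v[idx[[o]], ] <- x$value * rep(w$value[o, ], each = nrow(x$value))
  }
  if (!is.null(b)) v <- sweep(v, 2L, as.numeric(b$value), "+")
  spo <- c(n, 2L * h, 2L * wd)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_node(with_sp(v, spo), parents, function(g) {
    dX <- matrix(0, n * h * wd, cc)
    dW <- matrix(0, 4L, cc)
    for (o in 1:4) {
      go <- g[idx[[o]], , drop = FALSE]
      dX <- dX + go * rep(w$value[o, ], each = nrow(go))
      dW[o, ] <- colSums(x$value * go)
    }
    dX <- with_sp(dX, sp)
    if (is.null(b)) list(dX, dW) else list(dX, dW, colSums(g))
  })
}

## ---- normalization, dropout, concat ---------------------------------------

#' Batch normalization over the batch and spatial axes
#'
#' In training mode normalizes with batch statistics and updates the moving
#' statistics held in the (non-trainable) `rmean`/`rvar` parameter nodes as a
#' side effect; in inference mode normalizes with the moving statistics.
#' @keywords internal
ag_batchnorm <- function(x, gamma, beta, rmean, rvar, training = FALSE,
                         momentum = 0.99, eps = 1e-3) {
  sp <- attr(x$value, "sp")
  m <- nrow(x$value)
  if (training) {
    mu <- colMeans(x$value)
    xc <- sweep(x$value, 2L, mu, "-")
    va <- colMeans(xc * xc)
    iv <- 1 / sqrt(va + eps)
    xhat <- sweep(xc, 2L, iv, "*")
    rmean$value <- momentum * rmean$value + (1 - momentum) * mu
    rvar$value <- momentum * rvar$value + (1 - momentum) * va
    v <- sweep(sweep(xhat, 2L, as.numeric(gamma$value), "*"),
               2L, as.numeric(beta$value), "+")
    attr(v, "sp") <- sp
    new_node(v, list(x, gamma, beta), function(g) {
      dbeta <- colSums(g)
      dgamma <- colSums(g * xhat)
      giv <- as.numeric(gamma$value) * iv
      dX <- sweep(g, 2L, dbeta / m, "-") -
        sweep(xhat, 2L, dgamma / m, "*")
      dX <- sweep(dX, 2L, giv, "*")
      attr(dX, "sp") <- sp
      list(dX, dgamma, dbeta)
    })
  } else {
    iv <- 1 / sqrt(rvar$value + eps)
    scale <- as.numeric(gamma$value) * as.numeric(iv)
    shift <- as.numeric(beta$value) - as.numeric(rmean$value) * scale
    v <- sweep(sweep(x$value, 2L, scale, "*"), 2L, shift, "+")
    attr(v, "sp") <- sp
    new_node(v, list(x, gamma, beta), function(g) {
      xhat <- sweep(x$value, 2L, as.numeric(rmean$value), "-")
      xhat <- sweep(xhat, 2L, as.numeric(iv), "*")
      dX <- sweep(g, 2L, scale, "*")
      attr(dX, "sp") <- sp
      list(dX, colSums(g * xhat), colSums(g))
    })
  }
}

#' Inverted dropout (scales kept activations by 1/(1-rate))
#' @keywords internal
ag_dropout <- function(x, rate, training = FALSE) {
  if (!training || rate <= 0) return(x)
  keep <- (stats::runif(length(x$value)) >= rate) / (1 - rate)
  dim(keep) <- dim(x$value)
  v <- x$value * keep
  attr(v, "sp") <- attr(x$value, "sp")
  new_node(v, list(x), function(g) list(g * keep))
}

#' Channel concatenation
#' @keywords internal
ag_concat <- function(x, y) {
  sp <- attr(x$value, "sp")
  cx <- ncol(x$value)
  v <- cbind(x$value, y$value)
  attr(v, "sp") <- sp
  new_node(v, list(x, y), function(g) {
    gx <- g[, seq_len(cx), drop = FALSE]
    gy <- g[, -seq_len(cx), drop = FALSE]
    attr(gx, "sp") <- sp
    attr(gy, "sp") <- attr(y$value, "sp")
    list(gx, gy)
  })
}

## ---- attention primitives --------------------------------------------------

sample_groups <- function(n, hw) rep.int(seq_len(n), hw)

#' Global average pool over space: (n*h*w, C) -> (n, C)
#' @keywords internal
ag_global_avgpool <- function(x) {
  sp <- ag_sp(x)
  n <- sp[1]; hw <- sp[2] * sp[3]
  grp <- sample_groups(n, hw)
  v <- rowsum(x$value, grp, reorder = TRUE) / hw
  new_node(v, list(x), function(g) {
    dX <- g[grp, , drop = FALSE] / hw
    list(with_sp(dX, sp))
  })
}

#' Global max pool over space: (n*h*w, C) -> (n, C)
#' @keywords internal
ag_global_maxpool <- function(x) {
  sp <- ag_sp(x)
  n <- sp[1]; hw <- sp[2] * sp[3]
  cc <- ncol(x$value)
  v <- matrix(-Inf, n, cc)
  arg <- matrix(1L, n, cc)
  for (s in seq_len(n)) {
    rows <- seq.int(s, by = n, length.out = hw)
    sub <- t(x$value[rows, , drop = FALSE])   # C x hw
    am <- max.col(sub, ties.method = "first")
    v[s, ] <- sub[cbind(seq_len(cc), am)]
    arg[s, ] <- rows[am]
  }
  new_node(v, list(x), function(g) {
    dX <- matrix(0, nrow(x$value), cc)
    for (ch in seq_len(cc)) {
      dX[cbind(arg[, ch], ch)] <- dX[cbind(arg[, ch], ch)] + g[, ch]
    }
    list(with_sp(dX, sp))
  })
}

#' Per-pixel mean over channels: (n*h*w, C) -> (n*h*w, 1)
#' @keywords internal
ag_channel_mean <- function(x) {
  sp <- ag_sp(x)
  cc <- ncol(x$value)
  v <- with_sp(matrix(rowMeans(x$value), ncol = 1L), sp)
  new_node(v, list(x), function(g) {
    list(with_sp(matrix(g, nrow(x$value), cc) / cc, sp))
  })
}

#' Per-pixel max over channels: (n*h*w, C) -> (n*h*w, 1)
#' @keywords internal
ag_channel_max <- function(x) {
  sp <- ag_sp(x)
  am <- max.col(x$value, ties.method = "first")
  rows <- seq_len(nrow(x$value))
  v <- with_sp(matrix(x$value[cbind(rows, am)], ncol = 1L), sp)
  new_node(v, list(x), function(g) {
    dX <- matrix(0, nrow(x$value), ncol(x$value))
    dX[cbind(rows, am)] <- g
    list(with_sp(dX, sp))
  })
}

#' Scale each channel of a feature map by per-sample channel weights (n, C)
#' @keywords internal
ag_scale_channels <- function(x, w) {
  sp <- ag_sp(x)
  n <- sp[1]; hw <- sp[2] * sp[3]
  grp <- sample_groups(n, hw)
  wexp <- w$value[grp, , drop = FALSE]
  v <- with_sp(x$value * wexp, sp)
  new_node(v, list(x, w), function(g) {
    dX <- with_sp(g * wexp, sp)
    dW <- rowsum(g * x$value, grp, reorder = TRUE)
    list(dX, dW)
  })
}

#' Scale all channels of a feature map by a spatial map (n*h*w, 1)
#' @keywords internal
ag_scale_spatial <- function(x, m) {
  sp <- ag_sp(x)
  mv <- as.numeric(m$value)
  v <- with_sp(x$value * mv, sp)
  new_node(v, list(x, m), function(g) {
    dX <- with_sp(g * mv, sp)
    dM <- matrix(rowSums(g * x$value), ncol = 1L)
    list(dX, dM)
  })
}

## ---- loss ------------------------------------------------------------------

#' Soft dice loss node: mean over batch samples of 1 - (2*sum(p*o)+eps)/(sum(p)+sum(o)+eps)
#' @param pred node of probabilities, (n*h*w, 1)
#' @param target plain numeric matrix of {0,1}, same rows
#' @param smooth smoothing constant
#' @keywords internal
ag_dice_loss <- function(pred, target, smooth = 1.0) {
  sp <- ag_sp(pred)
  n <- sp[1]; hw <- sp[2] * sp[3]
  grp <- sample_groups(n, hw)
  p <- as.numeric(pred$value)
  o <- as.numeric(target)
  num <- 2 * rowsum(p * o, grp, reorder = TRUE)[, 1] + smooth
  den <- rowsum(p + o, grp, reorder = TRUE)[, 1] + smooth
  v <- matrix(mean(1 - num / den), 1L, 1L)
  new_node(v, list(pred), function(g) {
    gs <- as.numeric(g)
    dp <- (num[grp] - 2 * o * den[grp]) / (den[grp]^2) * (gs / n)
    list(with_sp(matrix(dp, ncol = 1L), sp))
  })
}
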