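#' Training protocol configuration
#'
#' Defaults follow the reference protocol: 150 epochs of Adamax at an
#' initial learning rate of 0.00025 with batch size 40, early stopping with
#' a patience of 15 epochs, and best-model selection on validation accuracy
#' (`val_dice` is offered because pixel accuracy saturates on
#' class-imbalanced masks).
#'
#' @param epochs maximum number of epochs
#' @param batch_size samples per optimization step (capped at the dataset
#'   size)
#' @param learning_rate Adamax step size
#' @param optimizer only `"adamax"` is provided
#' @param early_stop_patience epochs without monitor improvement before
#'   stopping; must not exceed `epochs`. Set to `epochs` to disable.
#' @param monitor `"val_accuracy"` or `"val_dice"`
#' @param dice_smooth smoothing constant of the soft dice loss
#' @param seed seed controlling shuffling, dropout and reproducibility
#' @return object of class `train_config`
#' @export
train_config <- function(epochs = 150L, batch_size = 40L,
                         learning_rate = 0.00025,
                         optimizer = "adamax",
                         early_stop_patience = 15L,
                         monitor = c("val_accuracy", "val_dice"),
                         dice_smooth = 1.0,
                         seed = 1L) {
  check_number(epochs, "epochs", lower = 1, integer = TRUE)
  check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_number(learning_rate, "learning_rate", lower = 0,
               strict_lower = TRUE)
  if (!identical(optimizer, "adamax")) {
    abort_field("optimizer", "only 'adamax' is provided")
  }
  check_number(early_stop_patience, "early_stop_patience", lower = 1,
               integer = TRUE)
  if (early_stop_patience > epochs) {
    abort_field("early_stop_patience", "must be <= epochs")
  }
  monitor <- match.arg(monitor)
  check_number(dice_smooth, "dice_smooth", lower = 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 early_stop_patience = as.integer(early_stop_patience),
                 monitor = monitor, dice_smooth = dice_smooth,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Soft dice loss
#'
#' `1 - (2 sum(p*o) + eps) / (sum(p) + sum(o) + eps)`: the complement of the
#' smoothed soft Dice coefficient between a probability map and a binary
#' target. Always in `[0,1]`; 0 only for a perfect (hard) match.
#'
#' @param predicted numeric array of probabilities in `[0,1]`
#' @param target binary array of the same shape
#' @param smooth smoothing constant `eps` (default 1, stabilizing empty
#'   masks)
#' @return scalar loss
#' @export
#' @examples
#' dice_loss(matrix(0.5, 2, 2), matrix(c(1, 1, 0, 0), 2))  # about 0.5
dice_loss <- function(predicted, target, smooth = 1.0) {
  check_same_shape(predicted, target, "predicted and target")
  num <- 2 * sum(predicted * target) + smooth
  den <- sum(predicted) + sum(target) + smooth
  1 - num / den
}

## Adamax: infinity-norm variant of Adam (Keras defaults).
adamax_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$m <- lapply(params, function(p) p$value * 0)
  st$u <- lapply(params, function(p) p$value * 0)
  st
}

adamax_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-7) {
  st$t <- st$t + 1
  corr <- lr / (1 - beta1^st$t)
  for (k in seq_along(params)) {
    p <- params[[k]]
    if (is.null(p$grad)) next
    g <- p$grad
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g
    st$u[[k]] <- pmax(beta2 * st$u[[k]], abs(g))
    p$value <- p$value - corr * st$m[[k]] / (st$u[[k]] + eps)
  }
  invisible(st)
}

hard_metrics_from_probs <- function(pv, target, sp) {
  pred <- (pv >= 0.5) * 1
  inter <- sum(pred * target)
  s1 <- sum(pred); s2 <- sum(target)
  uni <- s1 + s2 - inter
  c(accuracy = mean(pred == target),
    dice = if (s1 + s2 == 0) 1 else 2 * inter / (s1 + s2),
    iou = if (uni == 0) 1 else inter / uni)
}

targets_matrix <- function(samples) {
  n <- length(samples)
  d <- dim(samples[[1]]$mask)
  arr <- array(0, c(n, d[1], d[2]))
  for (s in seq_len(n)) arr[s, , ] <- samples[[s]]$mask
  dim(arr) <- c(n * d[1] * d[2], 1L)
  arr
}

eval_on_set <- function(network, samples, smooth) {
  x <- as_feature_matrix(lapply(samples, function(s) s$image))
  tgt <- targets_matrix(samples)
  out <- ag_no_grad(network$forward(ag_input(x), training = FALSE))
  c(loss = dice_loss(out$value, tgt, smooth),
    hard_metrics_from_probs(out$value, tgt, attr(out$value, "sp")))
}

#' Train a segmentation network
#'
#' Minimizes the soft dice loss with Adamax. The per-epoch history records
#' loss, pixel accuracy, Dice and IoU on the training batches (computed with
#' the batch statistics seen during the step, as training-mode metrics
#' usually are) and on the validation set (inference mode). Early stopping
#' halts training after `early_stop_patience` epochs without strict monitor
#' improvement; the parameters of the best monitored epoch are restored.
#'
#' @param network a `seg_network` (modified in place and returned)
#' @param train_set,val_set non-empty lists of [mri_sample()] with masks
#' @param config a [train_config()]
#' @return object of class `train_result`: list with `network`, `history`
#'   (data.frame, one row per completed epoch), `best_epoch`,
#'   `stopped_epoch`, `steps` (total optimization steps)
#' @export
train <- function(network, train_set, val_set, config = train_config()) {
  stopifnot(inherits(network, "seg_network"), inherits(config, "train_config"))
  if (!length(train_set) || !length(val_set)) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  params <- network$net$params
  trainable <- Filter(function(p) p$trainable, params)
  st <- adamax_state(trainable)
  monitor_key <- config$monitor
  best_val <- -Inf
  best_epoch <- 0L
  best_state <- NULL
  wait <- 0L
  history <- NULL
  steps <- 0L
  n <- length(train_set)
  bs <- min(config$batch_size, n)
  stopped <- config$epochs
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep <- c(loss = 0, accuracy = 0, dice = 0, iou = 0)
      nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        batch <- train_set[idx]
        x <- as_feature_matrix(lapply(batch, function(s) s$image))
        tgt <- targets_matrix(batch)
        out <- network$forward(ag_input(x), training = TRUE)
        loss <- ag_dice_loss(out, tgt, config$dice_smooth)
        if (!is.finite(loss$value)) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               call. = FALSE)
        }
        ag_backward(loss)
        adamax_step(trainable, st, config$learning_rate)
        steps <- steps + 1L
        nb <- nb + 1L
        ep <- ep + c(loss = as.numeric(loss$value),
                     hard_metrics_from_probs(out$value, tgt, NULL))
      }
      ep <- ep / nb
      vm <- eval_on_set(network, val_set, config$dice_smooth)
      history <- rbind(history, data.frame(
        epoch = epoch, loss = ep["loss"], accuracy = ep["accuracy"],
        dice = ep["dice"], iou = ep["iou"],
        val_loss = vm["loss"], val_accuracy = vm["accuracy"],
        val_dice = vm["dice"], val_iou = vm["iou"], row.names = NULL))
      mv <- unname(vm[sub("^val_", "", monitor_key)])
      if (mv > best_val) {
        best_val <- mv
        best_epoch <- epoch
        best_state <- lapply(trainable, function(p) p$value)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) {
          stopped <- epoch
          break
        }
      }
    }
  })
  if (!is.null(best_state)) {
    for (k in seq_along(trainable)) trainable[[k]]$value <- best_state[[k]]
  }
  structure(list(network = network, history = history,
                 best_epoch = best_epoch, stopped_epoch = stopped,
                 steps = steps),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(paste0("<train_result: %d epoch(s), %d step(s), best epoch %d",
                     " | final train dice %.4f, val dice %.4f>\n"),
              nrow(x$history), x$steps, x$best_epoch, last$dice,
              last$val_dice))
  invisible(x)
}
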