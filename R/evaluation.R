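#' Pixel accuracy
#'
#' Proportion of pixels whose predicted label equals the ground truth.
#'
#' @param pred,truth binary matrices of identical shape
#' @return fraction in `[0,1]`
#' @export
pixel_accuracy <- function(pred, truth) {
  check_same_shape(pred, truth, "pred and truth")
  mean(pred == truth)
}

#' Dice similarity coefficient (DSC)
#'
#' `2 |P intersect O| / (|P| + |O|)` for predicted set P and ground-truth set
#' O; equivalent to the F1 score on pixel sets. When both masks are empty the
#' coefficient is defined as 1 (a correct all-negative prediction).
#'
#' @param pred,truth binary matrices of identical shape
#' @return fraction in `[0,1]`
#' @export
#' @examples
#' p <- matrix(c(1, 1, 1, 0), 2); o <- matrix(c(1, 1, 0, 1), 2)
#' dice_coefficient(p, o)  # 2*2/(3+3)
dice_coefficient <- function(pred, truth) {
  check_same_shape(pred, truth, "pred and truth")
  sp <- sum(pred)
  so <- sum(truth)
  if (sp + so == 0) return(1)
  2 * sum(pred * truth) / (sp + so)
}

#' Intersection over union (IoU, Jaccard index)
#'
#' `|P intersect O| / |P union O|`; 1 when both masks are empty. Related to
#' the Dice coefficient by `DSC = 2 IoU / (1 + IoU)`.
#'
#' @param pred,truth binary matrices of identical shape
#' @return fraction in `[0,1]`
#' @export
iou <- function(pred, truth) {
  check_same_shape(pred, truth, "pred and truth")
  inter <- sum(pred * truth)
  uni <- sum(pred) + sum(truth) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Per-sample and aggregate segmentation metrics
#'
#' Computes accuracy, Dice and IoU for each (prediction, truth) pair. In
#' `"slice"` mode (default) the aggregate is the mean of the per-slice
#' metrics; in `"pooled"` mode the pixel counts are pooled over the whole
#' set before the metrics are formed.
#'
#' @param preds,truths lists of binary matrices
#' @param ids sample identifiers
#' @param mode `"slice"` or `"pooled"`
#' @return object of class `metric_report`: list with `per_sample`
#'   (data.frame), `aggregate` (named numeric), `mode`
#' @export
metric_report <- function(preds, truths, ids = NULL,
                          mode = c("slice", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(length(preds) == length(truths), length(preds) >= 1L)
  if (is.null(ids)) ids <- sprintf("sample_%04d", seq_along(preds) - 1L)
  per <- data.frame(
    id = ids,
    accuracy = mapply(pixel_accuracy, preds, truths),
    dice = mapply(dice_coefficient, preds, truths),
    iou = mapply(iou, preds, truths))
  rownames(per) <- NULL
  aggregate <- if (mode == "slice") {
    c(accuracy = mean(per$accuracy), dice = mean(per$dice),
      iou = mean(per$iou))
  } else {
    inter <- sum(mapply(function(p, o) sum(p * o), preds, truths))
    sp <- sum(vapply(preds, sum, numeric(1)))
    so <- sum(vapply(truths, sum, numeric(1)))
    npx <- sum(vapply(preds, length, numeric(1)))
    correct <- sum(mapply(function(p, o) sum(p == o), preds, truths))
    uni <- sp + so - inter
    c(accuracy = correct / npx,
      dice = if (sp + so == 0) 1 else 2 * inter / (sp + so),
      iou = if (uni == 0) 1 else inter / uni)
  }
  structure(list(per_sample = per, aggregate = aggregate, mode = mode),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report (%s mode, %d samples)>\n", x$mode,
              nrow(x$per_sample)))
  cat(sprintf("  accuracy %.4f | dice %.4f | iou %.4f\n",
              x$aggregate["accuracy"], x$aggregate["dice"],
              x$aggregate["iou"]))
  invisible(x)
}

#' Write a metric report as CSV (per-sample rows plus an aggregate footer)
#' @param report a [metric_report()]
#' @param file output path
#' @return invisibly, the written data.frame
#' @export
write_metric_report <- function(report, file) {
  out <- rbind(report$per_sample,
               data.frame(id = "aggregate",
                          accuracy = report$aggregate["accuracy"],
                          dice = report$aggregate["dice"],
                          iou = report$aggregate["iou"]))
  rownames(out) <- NULL
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Mean and standard deviation over repeated trials
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of a
#' metric evaluated over independent trials.
#'
#' @param values numeric vector with at least 2 trials
#' @return list with `mean`, `sd` and `n`
#' @export
#' @examples
#' summarize_trials(c(1, 2, 3))  # mean 2, sd 1
summarize_trials <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop("at least 2 trial values are required", call. = FALSE)
  }
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}
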