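#' Fixed-threshold segmentation rule
#'
#' Classifies each pixel by comparing it with a threshold: the output is 1
#' where `f(x,y) >= T` and 0 where `f(x,y) < T` (pixels exactly at the
#' threshold belong to the foreground).
#'
#' @param image numeric matrix of intensities
#' @param T threshold value
#' @return binary matrix of the same shape
#' @export
#' @examples
#' apply_threshold(matrix(c(0, 255), 1), 128)  # 0 1
apply_threshold <- function(image, T) {
  check_number(T, "T")
  (image >= T) * 1
}

threshold_result <- function(threshold, iterations, converged) {
  structure(list(threshold = threshold, iterations = as.integer(iterations),
                 converged = isTRUE(converged)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result: T = %g, %d iteration(s), %sconverged>\n",
              x$threshold, x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Iterative (isodata) optimal threshold
#'
#' Iterates `T <- (mu1 + mu2) / 2`, where `mu1` is the mean of the foreground
#' pixels (`>= T`) and `mu2` the mean of the background pixels (`< T`),
#' until the threshold moves by no more than `tolerance`. The fixed point is
#' the isodata optimal threshold.
#'
#' @param image numeric matrix with at least two distinct values
#' @param initial_T starting threshold; defaults to the global mean
#' @param tolerance convergence tolerance in intensity units (default 0.5,
#'   below the quantization step of 8-bit data)
#' @param max_iterations safety cap on the number of updates
#' @return a `threshold_result` with the threshold, the number of updates
#'   performed (>= 1) and a convergence flag
#' @export
#' @examples
#' isodata_threshold(matrix(c(0, 0, 255, 255), 2))$threshold  # 127.5
isodata_threshold <- function(image, initial_T = mean(image),
                              tolerance = 0.5, max_iterations = 256L) {
  if (length(unique(as.numeric(image))) < 2L) {
    stop("degenerate histogram: image has fewer than 2 distinct values",
         call. = FALSE)
  }
  check_number(tolerance, "tolerance", lower = 0)
  x <- as.numeric(image)
  ## keep the threshold interior so both classes stay non-empty
  t_old <- min(max(initial_T, min(x) + .Machine$double.eps), max(x))
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iterations) {
    fg <- x[x >= t_old]
    bg <- x[x < t_old]
    if (!length(bg)) bg <- min(x)
    if (!length(fg)) fg <- max(x)
    t_new <- (mean(fg) + mean(bg)) / 2
    iterations <- iterations + 1L
    if (abs(t_new - t_old) <= tolerance) {
      t_old <- t_new
      converged <- TRUE
      break
    }
    t_old <- t_new
  }
  threshold_result(t_old, iterations, converged)
}

#' Class means and variance decomposition at a threshold
#'
#' Splits the pixels into background (`< T`) and foreground (`>= T`) and
#' returns the class weights, means, the weighted within-class variance, the
#' between-class variance and the total variance (all population variances).
#' The identity `total = within + between` holds for every threshold.
#'
#' @param image numeric matrix
#' @param T threshold
#' @return list with `w0`, `w1`, `mu0`, `mu1`, `within`, `between`, `total`
#' @export
threshold_variances <- function(image, T) {
  x <- as.numeric(image)
  n <- length(x)
  bg <- x[x < T]
  fg <- x[x >= T]
  w0 <- length(bg) / n
  w1 <- length(fg) / n
  mu0 <- if (length(bg)) mean(bg) else 0
  mu1 <- if (length(fg)) mean(fg) else 0
  v0 <- if (length(bg)) mean((bg - mu0)^2) else 0
  v1 <- if (length(fg)) mean((fg - mu1)^2) else 0
  list(w0 = w0, w1 = w1, mu0 = mu0, mu1 = mu1,
       within = w0 * v0 + w1 * v1,
       between = w0 * w1 * (mu1 - mu0)^2,
       total = mean((x - mean(x))^2))
}

#' Otsu's optimal threshold
#'
#' Scans every distinct intensity level as a candidate threshold and returns
#' the one maximizing the between-class variance (equivalently, minimizing
#' the weighted within-class variance). Ties are broken toward the lowest
#' level. Pixels equal to the threshold belong to the foreground class,
#' mirroring the `>=` branch of the thresholding rule.
#'
#' @param image numeric matrix with at least two distinct levels
#' @return a `threshold_result` (iterations = number of candidates scanned)
#' @export
#' @examples
#' otsu_threshold(matrix(c(0, 0, 0, 255, 255, 255), 2))$threshold  # 255
otsu_threshold <- function(image) {
  x <- as.numeric(image)
  levels_ <- sort(unique(x))
  if (length(levels_) < 2L) {
    stop("degenerate histogram: image has fewer than 2 distinct values",
         call. = FALSE)
  }
  n <- length(x)
  cnt <- as.numeric(table(factor(x, levels = levels_)))
  csum <- cumsum(cnt)
  cmean <- cumsum(cnt * levels_)
  total_mean <- cmean[length(cmean)] / n
  best <- -1  # between-class variance is non-negative
  best_level <- levels_[1]
  ## candidate T = levels_[k]: background = levels below k (strictly < T)
  for (k in seq_along(levels_)) {
    n0 <- if (k > 1L) csum[k - 1L] else 0
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- cmean[k - 1L] / n0
    mu1 <- (cmean[length(cmean)] - cmean[k - 1L]) / n1
    between <- (n0 / n) * (n1 / n) * (mu1 - mu0)^2
    if (between > best + 1e-15 * max(1, abs(best))) {
      best <- between
      best_level <- levels_[k]
    }
  }
  threshold_result(best_level, length(levels_), TRUE)
}

#' Segment an image with a classical thresholding method
#'
#' @param image numeric matrix
#' @param method `"isodata"` or `"otsu"`
#' @param ... passed to the threshold estimator
#' @return list with `mask` (binary matrix) and `result`
#'   (a `threshold_result`)
#' @export
threshold_segment <- function(image, method = c("isodata", "otsu"), ...) {
  method <- match.arg(method)
  res <- switch(method,
                isodata = isodata_threshold(image, ...),
                otsu = otsu_threshold(image, ...))
  list(mask = apply_threshold(image, res$threshold), result = res)
}
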