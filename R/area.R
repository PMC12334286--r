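#' Physical pixel spacing
#'
#' The physical size of one pixel in millimetres along the image x (column)
#' and y (row) axes, as stored in MRI/DICOM metadata. Anisotropic spacing
#' (`sx != sy`) is supported.
#'
#' @param sx,sy mm per pixel along x and y; both must be positive
#' @return object of class `pixel_spacing`
#' @export
#' @examples
#' pixel_area(pixel_spacing(0.5, 0.5))  # 0.25 mm^2
pixel_spacing <- function(sx, sy) {
  check_number(sx, "sx", lower = 0, strict_lower = TRUE)
  check_number(sy, "sy", lower = 0, strict_lower = TRUE)
  structure(list(sx = sx, sy = sy), class = "pixel_spacing")
}

#' Count tumor pixels in a binary mask
#'
#' The tumor pixel count is the sum of all mask values, with 1 marking tumor
#' pixels. The mask must be strictly binary.
#'
#' @param mask numeric matrix of 0/1
#' @return integer pixel count
#' @export
count_tumor_pixels <- function(mask) {
  if (!is_binary_mask(mask)) {
    stop("mask must be binary", call. = FALSE)
  }
  as.integer(round(sum(mask)))
}

#' Physical area of one pixel
#'
#' @param spacing a [pixel_spacing()]
#' @return pixel area in mm^2 (`sx * sy`)
#' @export
pixel_area <- function(spacing) {
  stopifnot(inherits(spacing, "pixel_spacing"))
  spacing$sx * spacing$sy
}

#' Physical tumor area of a segmented mask
#'
#' Multiplies the exact tumor pixel count by the physical area of one pixel.
#'
#' @param mask binary matrix
#' @param spacing a [pixel_spacing()]
#' @param id sample identifier carried into the result
#' @param min_blob_size if > 0, connected components (4-neighbourhood)
#'   smaller than this many pixels are removed before counting; off by
#'   default, since the pixel count formula counts every 1-pixel.
#' @return object of class `area_result`: list with `pixel_count`,
#'   `pixel_area` (mm^2), `tumor_area` (mm^2) and `sample_id`
#' @export
#' @examples
#' m <- matrix(0, 20, 20); m[5:14, 5:14] <- 1
#' tumor_area(m, pixel_spacing(0.5, 0.5))  # 100 px -> 25 mm^2
tumor_area <- function(mask, spacing, id = "sample", min_blob_size = 0L) {
  if (min_blob_size > 0L) {
    mask <- filter_small_components(mask, min_blob_size)
  }
  np <- count_tumor_pixels(mask)
  pa <- pixel_area(spacing)
  structure(list(pixel_count = np, pixel_area = pa, tumor_area = pa * np,
                 sample_id = as.character(id)),
            class = "area_result")
}

#' @export
print.area_result <- function(x, ...) {
  cat(sprintf("<area_result '%s': %d px x %g mm^2 = %g mm^2>\n",
              x$sample_id, x$pixel_count, x$pixel_area, x$tumor_area))
  invisible(x)
}

#' Remove connected components smaller than a minimum size
#'
#' 4-neighbourhood flood fill labelling; components with fewer than
#' `min_size` pixels are zeroed.
#'
#' @param mask binary matrix
#' @param min_size minimum component size in pixels
#' @return filtered binary matrix
#' @export
filter_small_components <- function(mask, min_size) {
  if (!is_binary_mask(mask)) stop("mask must be binary", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nl <- 0L
  out <- mask
  for (start in which(mask == 1)) {
    if (lab[start] != 0L) next
    nl <- nl + 1L
    queue <- start
    comp <- integer(0)
    lab[start] <- nl
    while (length(queue)) {
      px <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      comp <- c(comp, px)
      i <- ((px - 1L) %% h) + 1L
      j <- ((px - 1L) %/% h) + 1L
      for (nb in c(if (i > 1L) px - 1L, if (i < h) px + 1L,
                   if (j > 1L) px - h, if (j < w) px + h)) {
        if (mask[nb] == 1 && lab[nb] == 0L) {
          lab[nb] <- nl
          queue <- c(queue, nb)
        }
      }
    }
    if (length(comp) < min_size) out[comp] <- 0
  }
  out
}

#' Tabulate tumor areas over a set of segmented samples
#'
#' @param samples list; each element is either an [mri_sample()] with a mask
#'   or a list with elements `mask`, `spacing`, `id`
#' @param file optional path; when given the table is written as CSV
#' @return data.frame with columns id, pixel_count, pixel_area_mm2,
#'   area_mm2, ordered by id
#' @export
area_report <- function(samples, file = NULL) {
  if (length(samples) < 1L) {
    stop("at least one sample is required", call. = FALSE)
  }
  rows <- lapply(samples, function(s) {
    ar <- tumor_area(s$mask, s$spacing, id = s$id %||% "sample")
    data.frame(id = ar$sample_id, pixel_count = ar$pixel_count,
               pixel_area_mm2 = ar$pixel_area, area_mm2 = ar$tumor_area)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
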