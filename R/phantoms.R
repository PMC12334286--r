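#' Synthetic MRI phantom specification
#'
#' Describes a population of FLAIR-like 2-D phantom slices: a dark background
#' containing a brighter elliptical "brain" region with smooth texture, and
#' (with probability `tumor_probability`) one hyperintense elliptical lesion
#' with an analytically known ground-truth mask. Phantoms make the whole
#' segmentation and area-quantification pipeline testable without any
#' external imaging data.
#'
#' @param image_height,image_width image size in pixels
#' @param tumor_probability fraction in `[0,1]` of slices carrying a lesion
#' @param tumor_semi_axes_range `(min,max)` of the lesion semi-axes in pixels
#' @param tumor_contrast intensity offset of the lesion peak above the brain
#'   background, in `[0,1]` intensity units
#' @param background_texture_sigma amplitude of the smooth background texture
#' @param noise_sigma standard deviation of additive Gaussian pixel noise
#' @param pixel_spacing_x,pixel_spacing_y physical pixel size in mm
#' @param seed integer; the generator is bit-reproducible given
#'   `(spec, index)`
#' @return object of class `phantom_spec`
#' @export
#' @examples
#' spec <- phantom_spec(image_height = 64, image_width = 64, seed = 7)
#' s <- generate_phantom(spec, 0)
#' dim(s$image); sum(s$mask) == s$true_pixel_count
phantom_spec <- function(image_height = 128L, image_width = 128L,
                         tumor_probability = 0.7,
                         tumor_semi_axes_range = NULL,
                         tumor_contrast = 0.4,
                         background_texture_sigma = 0.05,
                         noise_sigma = 0.02,
                         pixel_spacing_x = 1.0, pixel_spacing_y = 1.0,
                         seed = 1L) {
  check_number(image_height, "image_height", lower = 8, integer = TRUE)
  check_number(image_width, "image_width", lower = 8, integer = TRUE)
  check_number(tumor_probability, "tumor_probability", lower = 0, upper = 1)
  check_number(tumor_contrast, "tumor_contrast", lower = 0, upper = 1)
  check_number(background_texture_sigma, "background_texture_sigma",
               lower = 0)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(pixel_spacing_x, "pixel_spacing_x", lower = 0,
               strict_lower = TRUE)
  check_number(pixel_spacing_y, "pixel_spacing_y", lower = 0,
               strict_lower = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (is.null(tumor_semi_axes_range)) {
    tumor_semi_axes_range <- c(round(min(image_height, image_width) / 16),
                               round(min(image_height, image_width) / 6))
  }
  if (length(tumor_semi_axes_range) != 2L ||
      any(tumor_semi_axes_range <= 0) ||
      tumor_semi_axes_range[1] > tumor_semi_axes_range[2]) {
    abort_field("tumor_semi_axes_range", "must be (min, max) with 0 < min <= max")
  }
  if (tumor_semi_axes_range[2] >= min(image_height, image_width) / 2) {
    abort_field("tumor_semi_axes_range",
                "max semi-axis must be < min(image dims)/2")
  }
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 tumor_probability = tumor_probability,
                 tumor_semi_axes_range = as.numeric(tumor_semi_axes_range),
                 tumor_contrast = tumor_contrast,
                 background_texture_sigma = background_texture_sigma,
                 noise_sigma = noise_sigma,
                 pixel_spacing_x = pixel_spacing_x,
                 pixel_spacing_y = pixel_spacing_y,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' One MRI slice with mask and pixel-spacing metadata
#'
#' @param image (h,w,3) array of intensities in `[0,1]` (a (h,w) matrix is
#'   replicated to 3 channels)
#' @param mask (h,w) binary matrix, 1 = tumor, or `NULL`
#' @param spacing a [pixel_spacing()]
#' @param id sample identifier
#' @param true_pixel_count optional generator-recorded tumor pixel count
#' @return object of class `mri_sample`
#' @export
mri_sample <- function(image, mask = NULL, spacing = pixel_spacing(1, 1),
                       id = "sample", true_pixel_count = NULL) {
  if (length(dim(image)) == 2L) {
    image <- array(rep(image, 3L), c(dim(image), 3L))
  }
  if (length(dim(image)) != 3L) {
    abort_field("image", "must be an (h,w) matrix or (h,w,channels) array")
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(image)[1:2])) {
      abort_field("mask", "spatial dimensions must match the image")
    }
    if (!is_binary_mask(mask)) {
      abort_field("mask", "mask must be binary")
    }
  }
  structure(list(image = image, mask = mask, spacing = spacing,
                 id = as.character(id), true_pixel_count = true_pixel_count),
            class = "mri_sample")
}

#' @export
print.mri_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<mri_sample '%s': %dx%dx%d, %s, spacing %gx%g mm>\n",
              x$id, d[1], d[2], d[3],
              if (is.null(x$mask)) "no mask"
              else sprintf("%d tumor px", sum(x$mask)),
              x$spacing$sx, x$spacing$sy))
  invisible(x)
}

#' Binary mask of pixels whose centers lie inside a rotated ellipse
#'
#' The membership rule `((u/a)^2 + (v/b)^2 <= 1)` evaluated at pixel centers
#' `(row, col)` is the generator's definition of ground truth, so tumor pixel
#' counts are exact integers.
#'
#' @param h,w grid size
#' @param cx,cy ellipse center (column, row) in pixel units
#' @param a,b semi-axes in pixels (a along the rotated x-axis)
#' @param theta rotation angle in radians
#' @return (h,w) binary matrix
#' @export
ellipse_mask <- function(h, w, cx, cy, a, b, theta = 0) {
  x <- matrix(rep(seq_len(w), each = h), h, w)  # column coordinate
  y <- matrix(rep(seq_len(h), w), h, w)         # row coordinate
  u <- cos(theta) * (x - cx) + sin(theta) * (y - cy)
  v <- -sin(theta) * (x - cx) + cos(theta) * (y - cy)
  ((u / a)^2 + (v / b)^2 <= 1) * 1
}

## smooth low-frequency texture from a few random sinusoids
phantom_texture <- function(h, w, sigma) {
  if (sigma <= 0) return(matrix(0, h, w))
  x <- matrix(rep(seq_len(w), each = h), h, w) / w
  y <- matrix(rep(seq_len(h), w), h, w) / h
  tex <- matrix(0, h, w)
  for (k in 1:3) {
    f <- stats::runif(2, 0.5, 3)
    ph <- stats::runif(1, 0, 2 * pi)
    tex <- tex + sin(2 * pi * (f[1] * x + f[2] * y) + ph)
  }
  sigma * tex / sqrt(3)
}

#' Generate one phantom slice
#'
#' Deterministic in `(spec, index)`: calling twice returns bit-identical
#' output. The returned sample records the exact tumor pixel count.
#'
#' @param spec a [phantom_spec()]
#' @param index non-negative sample index
#' @return an [mri_sample()] with 3-channel image in `[0,1]`, binary mask and
#'   the spec's pixel spacing
#' @export
generate_phantom <- function(spec, index = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_number(index, "index", lower = 0, integer = TRUE)
  h <- spec$image_height; w <- spec$image_width
  with_seed(derive_seed(spec$seed, index), {
    ## brain: large centered ellipse, slightly jittered
    bcx <- w / 2 + stats::runif(1, -w / 40, w / 40)
    bcy <- h / 2 + stats::runif(1, -h / 40, h / 40)
    ba <- 0.42 * w * stats::runif(1, 0.92, 1.0)
    bb <- 0.44 * h * stats::runif(1, 0.92, 1.0)
    brain <- ellipse_mask(h, w, bcx, bcy, ba, bb) == 1
    img <- matrix(0.02, h, w)
    img[brain] <- 0.35 + phantom_texture(h, w, spec$background_texture_sigma)[brain]

    has_tumor <- stats::runif(1) < spec$tumor_probability
    mask <- matrix(0, h, w)
    if (has_tumor) {
      ax <- stats::runif(1, spec$tumor_semi_axes_range[1],
                         spec$tumor_semi_axes_range[2])
      bx <- stats::runif(1, spec$tumor_semi_axes_range[1],
                         spec$tumor_semi_axes_range[2])
      theta <- stats::runif(1, 0, pi)
      ## center well inside the brain so the lesion sits on brain tissue
      tcx <- bcx + stats::runif(1, -0.45, 0.45) * (ba - ax)
      tcy <- bcy + stats::runif(1, -0.45, 0.45) * (bb - bx)
      mask <- ellipse_mask(h, w, tcx, tcy, ax, bx, theta)
      ## smooth hyperintense profile peaking at the lesion center
      x <- matrix(rep(seq_len(w), each = h), h, w)
      y <- matrix(rep(seq_len(h), w), h, w)
      u <- cos(theta) * (x - tcx) + sin(theta) * (y - tcy)
      v <- -sin(theta) * (x - tcx) + cos(theta) * (y - tcy)
      r2 <- (u / ax)^2 + (v / bx)^2
      img <- img + spec$tumor_contrast * exp(-r2 / 2) * (r2 <= 4)
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    img <- pmin(pmax(img, 0), 1)
    mri_sample(image = img, mask = mask,
               spacing = pixel_spacing(spec$pixel_spacing_x,
                                       spec$pixel_spacing_y),
               id = sprintf("phantom_%04d", as.integer(index)),
               true_pixel_count = as.integer(sum(mask)))
  })
}

#' Generate a phantom dataset
#'
#' @param spec a [phantom_spec()]
#' @param n number of slices (>= 1), indices `0..n-1`
#' @return list of [mri_sample()]
#' @export
generate_dataset <- function(spec, n) {
  check_number(n, "n", lower = 1, integer = TRUE)
  lapply(seq_len(n) - 1L, function(i) generate_phantom(spec, i))
}

#' Write a phantom dataset as paired PNGs plus a metadata table
#'
#' Writes `image_XXXX.png` (3-channel), `mask_XXXX.png` (binary) and
#' `metadata.csv` with columns id, has_tumor, pixel_spacing_x_mm,
#' pixel_spacing_y_mm, true_pixel_count.
#'
#' @param samples list of [mri_sample()]
#' @param dir output directory (created if missing)
#' @return invisibly, the metadata data.frame
#' @export
write_phantom_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    id = vapply(samples, function(s) s$id, character(1)),
    has_tumor = vapply(samples, function(s) sum(s$mask) > 0, logical(1)),
    pixel_spacing_x_mm = vapply(samples, function(s) s$spacing$sx, numeric(1)),
    pixel_spacing_y_mm = vapply(samples, function(s) s$spacing$sy, numeric(1)),
    true_pixel_count = vapply(samples, function(s) as.integer(sum(s$mask)),
                              integer(1)))
  for (k in seq_along(samples)) {
    s <- samples[[k]]
    png::writePNG(s$image, file.path(dir, sprintf("image_%s.png",
                                                  sub("^phantom_", "", s$id))))
    png::writePNG(s$mask, file.path(dir, sprintf("mask_%s.png",
                                                 sub("^phantom_", "", s$id))))
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Load a phantom-layout dataset from disk
#'
#' Reads the `image_*.png` / `mask_*.png` pairs and `metadata.csv` written by
#' [write_phantom_dataset()].
#'
#' @param dir dataset directory
#' @return list of [mri_sample()]
#' @export
load_phantom_dataset <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop("no metadata.csv found in ", dir, call. = FALSE)
  }
  meta <- utils::read.csv(meta_path)
  lapply(seq_len(nrow(meta)), function(k) {
    tag <- sub("^phantom_", "", meta$id[k])
    img <- png::readPNG(file.path(dir, sprintf("image_%s.png", tag)))
    msk <- png::readPNG(file.path(dir, sprintf("mask_%s.png", tag)))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    mri_sample(image = img, mask = (msk >= 0.5) * 1,
               spacing = pixel_spacing(meta$pixel_spacing_x_mm[k],
                                       meta$pixel_spacing_y_mm[k]),
               id = meta$id[k],
               true_pixel_count = meta$true_pixel_count[k])
  })
}
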