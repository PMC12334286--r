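#' Min-max intensity normalization to [0,1]
#'
#' Rescales `(I - min(I)) / (max(I) - min(I))` elementwise. A constant image
#' is degenerate (max = min); it is mapped to all zeros with a warning.
#'
#' @param raw_image numeric array of any range
#' @return array of the same shape with values in `[0,1]`
#' @export
#' @examples
#' normalize_intensity(matrix(c(50, 150, 250), 1))  # 0, 0.5, 1
normalize_intensity <- function(raw_image) {
  if (length(raw_image) == 0L) {
    stop("raw_image must be non-empty", call. = FALSE)
  }
  lo <- min(raw_image)
  hi <- max(raw_image)
  if (hi == lo) {
    warning("constant image: min-max normalization is degenerate, ",
            "returning zeros")
    return(raw_image * 0)
  }
  (raw_image - lo) / (hi - lo)
}

## nearest-neighbour index map from target to source coordinates
nn_index <- function(target_n, source_n) {
  pmin(floor((seq_len(target_n) - 1L) * source_n / target_n) + 1L, source_n)
}

#' Resize a sample with nearest-neighbour interpolation
#'
#' Image and mask are resized with the same nearest-neighbour index map, so
#' the mask stays binary. Pixel spacing is rescaled by `orig_dim/target_dim`
#' per axis, preserving the physical extent of the slice.
#'
#' @param sample an [mri_sample()]
#' @param target_h,target_w target size in pixels
#' @return resized [mri_sample()]
#' @export
resize_sample <- function(sample, target_h, target_w) {
  stopifnot(inherits(sample, "mri_sample"))
  check_number(target_h, "target_h", lower = 1, integer = TRUE)
  check_number(target_w, "target_w", lower = 1, integer = TRUE)
  d <- dim(sample$image)
  ri <- nn_index(target_h, d[1])
  ci <- nn_index(target_w, d[2])
  img <- sample$image[ri, ci, , drop = FALSE]
  msk <- if (!is.null(sample$mask)) sample$mask[ri, ci, drop = FALSE]
  sp <- pixel_spacing(sample$spacing$sx * d[2] / target_w,
                      sample$spacing$sy * d[1] / target_h)
  mri_sample(img, msk, sp, sample$id,
             true_pixel_count = sample$true_pixel_count)
}

#' Dataset split specification
#'
#' @param train_fraction,val_fraction,test_fraction non-negative fractions
#'   summing to 1
#' @param seed shuffling seed
#' @return object of class `split_spec`
#' @export
split_spec <- function(train_fraction = 0.70, val_fraction = 0.15,
                       test_fraction = 0.15, seed = 1L) {
  for (f in c(train_fraction, val_fraction, test_fraction)) {
    if (!is.numeric(f) || f < 0) {
      abort_field("fractions", "must be non-negative")
    }
  }
  if (abs(train_fraction + val_fraction + test_fraction - 1) > 1e-9) {
    abort_field("fractions", "must sum to 1")
  }
  structure(list(train_fraction = train_fraction,
                 val_fraction = val_fraction,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split samples into train/validation/test sets
#'
#' Samples are shuffled seed-deterministically; the train and validation
#' sets take `floor(n * fraction)` samples each and the remainder goes to the
#' test set, so the three parts always form a disjoint cover.
#'
#' @param samples list of samples (>= 3)
#' @param spec a [split_spec()]
#' @return list with elements `train`, `val`, `test`
#' @export
#' @examples
#' sets <- split_dataset(as.list(1:100), split_spec(seed = 4))
#' lengths(sets)  # 70 / 15 / 15
split_dataset <- function(samples, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(samples)
  if (n < 3L) stop("need at least 3 samples to split", call. = FALSE)
  ord <- with_seed(spec$seed, sample.int(n))
  n_train <- floor(n * spec$train_fraction)
  n_val <- floor(n * spec$val_fraction)
  list(train = samples[ord[seq_len(n_train)]],
       val = samples[ord[n_train + seq_len(n_val)]],
       test = samples[ord[(n_train + n_val + 1L):n]])
}

#' Augmentation specification
#'
#' Two schemes are provided. The `"fixed"` scheme draws one transform from
#' the fixed rotation angles and axis flips. The `"random"` scheme (the
#' default, used during training) draws a random rotation of up to
#' `random_rotation_factor * 180` degrees, a random shift of up to
#' `shift_fraction` of each image dimension, and a random zoom within
#' `1 +/- zoom_fraction`; out-of-frame pixels are filled with the nearest
#' border pixel.
#'
#' @param scheme `"random"` or `"fixed"`
#' @param fixed_rotations rotation angles in degrees, each in (0, 360)
#' @param allow_flips include horizontal/vertical flips in the fixed scheme
#' @param random_rotation_factor unitless rotation amplitude (fraction of
#'   180 degrees)
#' @param shift_fraction,zoom_fraction amplitudes in `[0,1)`, fractions of
#'   the image size and of unit zoom
#' @param fill_mode only `"nearest"` is supported
#' @param seed base seed combined with the per-call draw seed
#' @return object of class `augment_spec`
#' @export
augment_spec <- function(scheme = c("random", "fixed"),
                         fixed_rotations = c(45, 90, 135),
                         allow_flips = TRUE,
                         random_rotation_factor = 0.2,
                         shift_fraction = 0.05,
                         zoom_fraction = 0.05,
                         fill_mode = "nearest",
                         seed = 0L) {
  scheme <- match.arg(scheme)
  if (any(fixed_rotations <= 0 | fixed_rotations >= 360)) {
    abort_field("fixed_rotations", "angles must lie in (0, 360)")
  }
  check_number(random_rotation_factor, "random_rotation_factor", lower = 0)
  check_number(shift_fraction, "shift_fraction", lower = 0)
  check_number(zoom_fraction, "zoom_fraction", lower = 0)
  if (shift_fraction >= 1 || zoom_fraction >= 1) {
    abort_field("shift_fraction/zoom_fraction", "must be in [0,1)")
  }
  if (!identical(fill_mode, "nearest")) {
    abort_field("fill_mode", "only 'nearest' is supported")
  }
  structure(list(scheme = scheme, fixed_rotations = fixed_rotations,
                 allow_flips = isTRUE(allow_flips),
                 random_rotation_factor = random_rotation_factor,
                 shift_fraction = shift_fraction,
                 zoom_fraction = zoom_fraction,
                 fill_mode = fill_mode, seed = as.integer(seed)),
            class = "augment_spec")
}

#' Rotate a matrix by a multiple of 90 degrees (exact pixel permutation)
#'
#' Counter-clockwise in the visual sense: the top-left pixel of a 2x2 matrix
#' moves to the bottom-left after `k = 1`.
#'
#' @param m matrix
#' @param k number of quarter turns
#' @return rotated matrix
#' @export
rot90_mat <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

## Inverse-mapped affine resampling with nearest-neighbour sampling and
## nearest-border fill. theta in degrees (visual counter-clockwise), shift in
## pixels (applied after rotation and zoom), zoom > 0.
affine_nearest <- function(m, theta = 0, shift_x = 0, shift_y = 0, zoom = 1) {
  h <- nrow(m); w <- ncol(m)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  th <- theta * pi / 180
  u <- matrix(rep(seq_len(w), each = h), h, w) - cx  # x, columns
  v <- matrix(rep(seq_len(h), w), h, w) - cy         # y, rows
  u0 <- u - shift_x
  v0 <- v - shift_y
  us <- (cos(th) * u0 - sin(th) * v0) / zoom
  vs <- (sin(th) * u0 + cos(th) * v0) / zoom
  sj <- pmin(pmax(round(us + cx), 1), w)
  si <- pmin(pmax(round(vs + cy), 1), h)
  matrix(m[cbind(as.vector(si), as.vector(sj))], h, w)
}

apply_geom <- function(sample, fn) {
  d <- dim(sample$image)
  img <- sample$image
  for (ch in seq_len(d[3])) img[, , ch] <- fn(sample$image[, , ch])
  msk <- if (!is.null(sample$mask)) (fn(sample$mask) >= 0.5) * 1
  mri_sample(img, msk, sample$spacing, sample$id)
}

#' Apply one augmentation draw to a sample
#'
#' The identical geometric transform is applied to the image and the mask;
#' the mask is re-binarized at 0.5 afterwards. Rotations by exact multiples
#' of 90 degrees are pixel permutations (no resampling).
#'
#' @param sample an [mri_sample()]
#' @param spec an [augment_spec()]
#' @param draw_seed integer identifying the draw; the same
#'   `(sample, spec, draw_seed)` always yields the same output
#' @return augmented [mri_sample()]
#' @export
augment <- function(sample, spec = augment_spec(), draw_seed = 0L) {
  stopifnot(inherits(sample, "mri_sample"), inherits(spec, "augment_spec"))
  with_seed(derive_seed(spec$seed, draw_seed), {
    if (spec$scheme == "fixed") {
      choices <- c(paste0("rot", spec$fixed_rotations),
                   if (spec$allow_flips) c("fliph", "flipv"))
      pick <- choices[[sample.int(length(choices), 1L)]]
      fn <- if (pick == "fliph") {
        function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
      } else if (pick == "flipv") {
        function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
      } else {
        ang <- as.numeric(sub("^rot", "", pick))
        if (ang %% 90 == 0) {
          function(m) rot90_mat(m, ang %/% 90)
        } else {
          function(m) affine_nearest(m, theta = ang)
        }
      }
      apply_geom(sample, fn)
    } else {
      d <- dim(sample$image)
      theta <- stats::runif(1, -1, 1) * spec$random_rotation_factor * 180
      sx <- stats::runif(1, -1, 1) * spec$shift_fraction * d[2]
      sy <- stats::runif(1, -1, 1) * spec$shift_fraction * d[1]
      z <- 1 + stats::runif(1, -1, 1) * spec$zoom_fraction
      apply_geom(sample, function(m) {
        affine_nearest(m, theta = theta, shift_x = sx, shift_y = sy, zoom = z)
      })
    }
  })
}

#' Flip a sample along an axis (exact pixel permutation)
#' @param sample an [mri_sample()]
#' @param axis `"horizontal"` (reverse columns) or `"vertical"` (reverse rows)
#' @return flipped [mri_sample()]
#' @export
flip_sample <- function(sample, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  fn <- if (axis == "horizontal") {
    function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  } else {
    function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  apply_geom(sample, fn)
}

#' Read an image file as a [0,1] intensity array
#'
#' PNG and TIFF are decoded with the png/tiff packages; single-channel images
#' are returned as (h,w) matrices, otherwise (h,w,3).
#'
#' @param path file path (.png, .tif/.tiff)
#' @return numeric array in `[0,1]`
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to read TIFF files",
             call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
  img
}

#' Read a binary mask from an image file (thresholded at 0.5)
#' @param path file path
#' @return (h,w) binary matrix
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  (m >= 0.5) * 1
}
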