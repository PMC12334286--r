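## Shared fixture builders (all fixtures are generated in code).

tiny_phantoms <- function(n = 4, size = 16, seed = 1, tumor_probability = 1) {
  generate_dataset(phantom_spec(image_height = size, image_width = size,
                                tumor_probability = tumor_probability,
                                seed = seed), n)
}

random_binary_mask <- function(h = 8, w = 8, p = 0.3) {
  matrix(as.numeric(stats::rbinom(h * w, 1, p)), h, w)
}

## independent exhaustive pixel-center-in-ellipse oracle (double loop,
## no shared code with ellipse_mask)
ellipse_oracle <- function(h, w, cx, cy, a, b, theta = 0) {
  m <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      u <- cos(theta) * (j - cx) + sin(theta) * (i - cy)
      v <- -sin(theta) * (j - cx) + cos(theta) * (i - cy)
      if ((u / a)^2 + (v / b)^2 <= 1) m[i, j] <- 1
    }
  }
  m
}

## count of mask pixels with at least one 4-neighbour outside the mask
boundary_pixel_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[2:(h + 1), 2:(w + 1)]
  nb_min <- pmin(pad[1:h, 2:(w + 1)], pad[3:(h + 2), 2:(w + 1)],
                 pad[2:(h + 1), 1:w], pad[2:(h + 1), 3:(w + 2)])
  sum(inner == 1 & nb_min == 0)
}
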