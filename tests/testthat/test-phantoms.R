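test_that("phantom generation is deterministic and well-formed", {
  spec <- phantom_spec(image_height = 32, image_width = 32, seed = 5)
  s1 <- generate_phantom(spec, 3)
  s2 <- generate_phantom(spec, 3)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)

  samples <- generate_dataset(spec, 8)
  expect_length(samples, 8)
  for (s in samples) {
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_true(all(s$mask %in% c(0, 1)))
    expect_identical(dim(s$image), c(32L, 32L, 3L))
    expect_identical(count_tumor_pixels(s$mask), s$true_pixel_count)
  }
})

test_that("tumor probability controls lesion occurrence", {
  none <- generate_dataset(phantom_spec(image_height = 24, image_width = 24,
                                        tumor_probability = 0, seed = 2), 5)
  expect_true(all(vapply(none, function(s) sum(s$mask) == 0, logical(1))))

  ## binomial 99% interval at n = 200, p = 0.5
  spec <- phantom_spec(image_height = 24, image_width = 24,
                       tumor_probability = 0.5, seed = 9)
  k <- sum(vapply(generate_dataset(spec, 200),
                  function(s) sum(s$mask) > 0, logical(1)))
  expect_gte(k, 80)
  expect_lte(k, 120)

  one <- generate_dataset(spec, 1)
  expect_length(one, 1)
  expect_error(generate_dataset(spec, 0), "n")
})

test_that("different seeds give different masks", {
  a <- generate_dataset(phantom_spec(image_height = 24, image_width = 24,
                                     seed = 1, tumor_probability = 1), 10)
  b <- generate_dataset(phantom_spec(image_height = 24, image_width = 24,
                                     seed = 2, tumor_probability = 1), 10)
  differs <- mapply(function(x, y) !identical(x$mask, y$mask), a, b)
  expect_true(any(differs))
})

test_that("mask matches the exhaustive pixel-center ellipse oracle", {
  ## the pixel-center rule makes counts exact; compare against an
  ## independent double-loop implementation and the analytic area
  m <- ellipse_mask(64, 64, 30.3, 33.1, 20, 10, theta = 0.4)
  expect_identical(m, ellipse_oracle(64, 64, 30.3, 33.1, 20, 10, 0.4))
  expect_lt(abs(sum(m) - pi * 20 * 10) / (pi * 20 * 10), 0.05)

  ## a generated phantom's mask is itself a pixel-center ellipse
  s <- generate_phantom(phantom_spec(image_height = 48, image_width = 48,
                                     tumor_probability = 1, seed = 3), 0)
  expect_identical(sum(s$mask), as.numeric(s$true_pixel_count))
})

test_that("lesion is hyperintense relative to its surround", {
  spec <- phantom_spec(image_height = 48, image_width = 48,
                       tumor_probability = 1, tumor_contrast = 0.4,
                       noise_sigma = 0.05, seed = 21)
  for (i in 0:4) {
    s <- generate_phantom(spec, i)
    inside <- mean(s$image[, , 1][s$mask == 1])
    outside <- mean(s$image[, , 1][s$mask == 0])
    expect_gte(inside - outside, 0.4 / 2)
  }
})

test_that("invalid phantom specifications name the offending field", {
  expect_error(phantom_spec(tumor_probability = 1.4), "tumor_probability")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(image_height = 64, image_width = 64,
                            tumor_semi_axes_range = c(10, 40)),
               "tumor_semi_axes_range")
  expect_error(phantom_spec(pixel_spacing_x = 0), "pixel_spacing_x")
})

test_that("phantom datasets round-trip through PNG files and metadata", {
  dir <- withr::local_tempdir()
  samples <- tiny_phantoms(3, size = 24, seed = 13)
  meta <- write_phantom_dataset(samples, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  loaded <- load_phantom_dataset(dir)
  expect_length(loaded, 3)
  for (k in 1:3) {
    expect_identical(loaded[[k]]$mask, samples[[k]]$mask)
    expect_equal(loaded[[k]]$spacing$sx, samples[[k]]$spacing$sx)
    ## 8-bit PNG quantization
    expect_lt(max(abs(loaded[[k]]$image - samples[[k]]$image)), 1 / 255)
  }
  expect_identical(meta$true_pixel_count,
                   vapply(samples, function(s) s$true_pixel_count,
                          integer(1)))
})
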