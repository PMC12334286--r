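test_that("area quantification follows pixel count times pixel area exactly", {
  m <- matrix(0, 20, 20); m[5:14, 5:14] <- 1  # 100 pixels
  r <- tumor_area(m, pixel_spacing(0.5, 0.5))
  expect_equal(r$pixel_count, 100L)
  expect_equal(r$pixel_area, 0.25)
  expect_identical(r$tumor_area, r$pixel_area * r$pixel_count)
  expect_equal(r$tumor_area, 25.0)

  expect_equal(tumor_area(matrix(0, 4, 4), pixel_spacing(3, 2))$tumor_area, 0)
  expect_equal(pixel_area(pixel_spacing(1, 1)), 1)
  expect_equal(pixel_area(pixel_spacing(0.8, 1.2)), 0.96)
  ## unit spacing: area numerically equals the count
  expect_equal(tumor_area(m, pixel_spacing(1, 1))$tumor_area, 100)
})

test_that("pixel counting validates binary masks", {
  expect_equal(count_tumor_pixels(diag(3)), 3L)
  expect_equal(count_tumor_pixels(matrix(0, 5, 5)), 0L)
  expect_error(count_tumor_pixels(matrix(c(0, 0.5, 1, 1), 2)),
               "mask must be binary")
  expect_error(pixel_spacing(-1, 1), "sx")
})

test_that("areas scale quadratically with spacing and add over disjoint masks", {
  set.seed(8)
  m <- random_binary_mask(16, 16, 0.3)
  base <- tumor_area(m, pixel_spacing(0.7, 1.1))$tumor_area
  for (k in c(0.5, 2, 3.25)) {
    scaled <- tumor_area(m, pixel_spacing(0.7 * k, 1.1 * k))$tumor_area
    expect_equal(scaled, k^2 * base, tolerance = 1e-12)
  }

  a <- matrix(0, 10, 10); a[1:3, 1:3] <- 1
  b <- matrix(0, 10, 10); b[7:9, 5:9] <- 1
  sp <- pixel_spacing(0.9, 1.3)
  expect_equal(tumor_area(a + b, sp)$tumor_area,
               tumor_area(a, sp)$tumor_area +
                 tumor_area(b, sp)$tumor_area, tolerance = 1e-12)
})

test_that("phantom areas equal the generator's recorded ground truth", {
  spec <- phantom_spec(image_height = 48, image_width = 48,
                       tumor_probability = 1, pixel_spacing_x = 0.8,
                       pixel_spacing_y = 1.1, seed = 14)
  samples <- generate_dataset(spec, 10)
  tab <- area_report(samples)
  expect_equal(nrow(tab), 10)
  truth <- vapply(samples, function(s) s$true_pixel_count * 0.8 * 1.1,
                  numeric(1))
  expect_equal(sort(tab$area_mm2), sort(truth), tolerance = 1e-12)
  expect_error(area_report(list()), "at least one")
})

test_that("resized convex phantoms keep their physical area within one boundary ring", {
  spec <- phantom_spec(image_height = 64, image_width = 64,
                       tumor_probability = 1, seed = 31)
  for (i in 0:2) {
    s <- generate_phantom(spec, i)
    orig <- tumor_area(s$mask, s$spacing)$tumor_area
    rs <- resize_sample(s, 32, 32)
    resized <- tumor_area(rs$mask, rs$spacing)$tumor_area
    ring <- boundary_pixel_count(rs$mask) * pixel_area(rs$spacing)
    expect_lt(abs(resized - orig), ring)
  }
})

test_that("small connected components can optionally be filtered", {
  m <- matrix(0, 12, 12)
  m[2, 2] <- 1                 # single-pixel speck
  m[5:8, 5:8] <- 1             # 16-pixel blob
  kept <- filter_small_components(m, 3)
  expect_equal(sum(kept), 16)
  expect_equal(tumor_area(m, pixel_spacing(1, 1))$tumor_area, 17)
  expect_equal(tumor_area(m, pixel_spacing(1, 1),
                          min_blob_size = 3)$tumor_area, 16)
})
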