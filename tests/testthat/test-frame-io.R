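test_that("frame stacks round-trip through multi-page TIFF bit-identically", {
  set.seed(42)
  arr <- array(sample(0:65535, 10 * 6 * 7, replace = TRUE), dim = c(10, 6, 7))
  st <- frame_stack(arr, frame_rate_hz = 9, source_id = "fixture")
  f <- withr::local_tempfile(fileext = ".tif")
  write_frame_stack(st, f)
  back <- load_frame_stack(f)
  expect_identical(dim(back$frames), dim(arr))
  expect_equal(back$frames, arr * 1.0, tolerance = 0)
  expect_equal(back$frame_rate_hz, 9)
})

test_that("a directory of single-frame images loads in filename order", {
  dir <- withr::local_tempdir()
  for (t in 1:5) {
    page <- matrix(t * 100 / 65535, 10, 10)
    tiff::writeTIFF(page, file.path(dir, sprintf("frame_%02d.tif", t)),
                    bits.per.sample = 16L)
  }
  st <- load_frame_stack(dir)
  expect_equal(dim(st$frames), c(5L, 10L, 10L))
  expect_equal(st$frames[, 1, 1], (1:5) * 100)
})

test_that("mixed frame shapes and too-few frames are rejected", {
  dir <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0.1, 10, 10), file.path(dir, "a.tif"), bits.per.sample = 16L)
  tiff::writeTIFF(matrix(0.1, 8, 8), file.path(dir, "b.tif"), bits.per.sample = 16L)
  expect_error(load_frame_stack(dir), class = "thermonet_format_error")

  dir2 <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0.1, 4, 4), file.path(dir2, "only.tif"), bits.per.sample = 16L)
  expect_error(load_frame_stack(dir2), class = "thermonet_insufficient_data")
})

test_that("crop_roi slices exactly and validates bounds", {
  arr <- array(seq_len(3 * 4 * 5), dim = c(3, 4, 5))
  st <- frame_stack(arr)
  # full-frame ROI is the identity
  expect_equal(crop_roi(st, roi_spec(1, 1, 5, 4))$frames, arr)
  # 1x1 ROI at the top-left pixel
  one <- crop_roi(st, roi_spec(1, 1, 1, 1))
  expect_equal(dim(one$frames), c(3L, 1L, 1L))
  expect_equal(as.vector(one$frames), arr[, 1, 1])
  # interior crop matches direct indexing
  sub <- crop_roi(st, roi_spec(2, 3, 3, 2))
  expect_equal(sub$frames, arr[, 3:4, 2:4, drop = FALSE])
  # past the right edge
  expect_error(crop_roi(st, roi_spec(4, 1, 3, 2)), class = "thermonet_bounds_error")
})

test_that("mean_series averages pixels per frame and respects affine maps", {
  st <- frame_stack(array(c(1, 2, 3, 6), dim = c(2, 1, 2)))
  expect_equal(mean_series(st)$values, c(2, 4))
  # constant frames give a constant series
  expect_equal(mean_series(uniform_stack(rep(7, 4)))$values, rep(7, 4))
  # mean(a*stack + b) = a*mean(stack) + b
  set.seed(7)
  arr <- array(runif(6 * 3 * 3, 1, 5), dim = c(6, 3, 3))
  m0 <- mean_series(frame_stack(arr))$values
  m1 <- mean_series(frame_stack(2.5 * arr + 3))$values
  expect_equal(m1, 2.5 * m0 + 3)
  # crop to full frame then mean equals mean directly
  st2 <- frame_stack(arr)
  expect_equal(mean_series(crop_roi(st2, roi_spec(1, 1, 3, 3)))$values, m0)
})

test_that("pca_series matches a brute-force eigendecomposition oracle", {
  set.seed(11)
  arr <- array(runif(20 * 4 * 4), dim = c(20, 4, 4))
  res <- pca_series(frame_stack(arr), k = 5)
  # oracle: eigenvalues of the pixel covariance matrix
  x <- scale(matrix(arr, nrow = 20), center = TRUE, scale = FALSE)
  ev <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(res$explained_fraction, (ev / sum(ev))[1:5], tolerance = 1e-9)
  expect_true(all(diff(res$explained_fraction) <= 1e-12))
  # explained fractions over all components sum to 1
  full <- pca_series(frame_stack(arr), k = 16)
  expect_equal(sum(full$explained_fraction), 1, tolerance = 1e-9)
})

test_that("rank-1 stacks put all variance on component 1, degenerate stacks error", {
  lvl <- c(5, 1, 4, 2, 8, 3)
  res <- pca_series(uniform_stack(lvl), k = 1)
  expect_equal(res$explained_fraction[1], 1, tolerance = 1e-9)
  m <- mean_series(uniform_stack(lvl))
  expect_equal(compare_reduction(m, res), 1, tolerance = 1e-9)
  # temporally constant stack: zero variance
  expect_error(pca_series(uniform_stack(rep(2, 5))),
               class = "thermonet_degenerate_input")
  expect_error(pca_series(uniform_stack(lvl), k = 0),
               class = "thermonet_parameter_error")
})

test_that("compare_reduction is a plain Pearson correlation with guards", {
  s <- temperature_series(c(1, 3, 2, 5))
  fake <- structure(list(component_series = matrix(-c(1, 3, 2, 5), ncol = 1),
                         explained_fraction = 1),
                    class = "pca_result")
  expect_equal(compare_reduction(s, fake), -1)
  const <- temperature_series(rep(2, 4))
  expect_error(compare_reduction(const, fake), class = "thermonet_degenerate_input")
})
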