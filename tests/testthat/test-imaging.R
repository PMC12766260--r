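table_3x2 <- function(values) {
  px <- expand.grid(x = 0:2, y = 0:1)
  px <- px[order(px$x, px$y), ]
  msi_features(values, 300 + seq_len(ncol(values)) * 50, px)
}

test_that("ion images place intensities at their raster coordinates", {
  m <- matrix(0, 6, 2)
  m[2, 1] <- 7  # pixel (x=0, y=1)
  t0 <- table_3x2(m)
  img <- ion_image(t0, 1)
  expect_equal(img$grid[1, 2], 7)
  expect_equal(sum(img$grid), sum(t0$matrix[, 1]))
  # all-zero feature -> all-zero image
  expect_true(all(ion_image(t0, 2)$grid == 0))
  expect_error(ion_image(t0, 5), "unknown feature")
  # lookup by m/z label
  expect_equal(ion_image(t0, "350.0000")$grid, img$grid)
})

test_that("a single non-zero weight collapses the component image", {
  set.seed(3)
  m <- matrix(rlnorm(12), 6, 2)
  t0 <- table_3x2(m)
  model <- structure(list(n_components = 1L,
                          contributions = matrix(c(0.8, 0), 1),
                          feature_mz = t0$feature_mz),
                     class = "fingerprint_model")
  img <- component_image(t0, model, 1, power = 5)
  expect_equal(img$grid, ion_image(t0, 1)$grid)
})

test_that("fifth-power weighting and normalization follow the definition", {
  set.seed(9)
  m <- matrix(rlnorm(12), 6, 2)
  t0 <- table_3x2(m)
  model <- structure(list(n_components = 1L,
                          contributions = matrix(c(1, 0.5), 1),
                          feature_mz = t0$feature_mz),
                     class = "fingerprint_model")
  img <- component_image(t0, model, 1, power = 5)
  w <- c(1, 0.5^5)  # 0.03125
  expected <- (m %*% w) / sum(w)
  expect_equal(img$grid[cbind(t0$pixels$x + 1, t0$pixels$y + 1)],
               as.numeric(expected), tolerance = 1e-12)
  # unnormalized variant
  img2 <- component_image(t0, model, 1, power = 5, normalize = FALSE)
  expect_equal(sum(img2$grid), sum(m %*% w))
})

test_that("component images ignore a global rescaling of the contributions", {
  set.seed(10)
  m <- matrix(rlnorm(18), 6, 3)
  t0 <- table_3x2(m)
  mk <- function(w) structure(list(n_components = 1L,
                                   contributions = matrix(w, 1),
                                   feature_mz = t0$feature_mz),
                              class = "fingerprint_model")
  i1 <- component_image(t0, mk(c(0.2, 0.5, 0.9)), 1)
  i2 <- component_image(t0, mk(10 * c(0.2, 0.5, 0.9)), 1)
  expect_equal(i1$grid, i2$grid, tolerance = 1e-12)
  expect_warning(component_image(t0, mk(c(0, 0, 0)), 1), "all-zero")
})

test_that("depth profiles conserve totals and smooth as specified", {
  set.seed(11)
  m <- matrix(rlnorm(40), 20, 2)
  px <- data.frame(x = rep(0:9, each = 2), y = rep(0:1, 10))
  t0 <- msi_features(m, c(300, 400), px)
  img <- ion_image(t0, 1)
  prof <- depth_profile(img, bin_um = 150, window = 5)
  expect_equal(sum(prof$raw_sums), sum(img$grid))
  expect_equal(prof$smoothed, oracle_moving_average(prof$raw_sums, 5))
  expect_length(prof$smoothed, length(prof$raw_sums))
  # window 1 is the identity
  p1 <- depth_profile(img, window = 1)
  expect_equal(p1$smoothed, p1$raw_sums)
  # constant image -> constant profile
  cimg <- img; cimg$grid[] <- 2
  pc <- depth_profile(cimg, window = 5)
  expect_true(all(pc$raw_sums == pc$raw_sums[1]))
  expect_equal(pc$smoothed, pc$raw_sums)
})

test_that("depth profile validates its window and bin size", {
  img <- structure(list(grid = matrix(1, 4, 2), provenance = "t",
                        pixel_pitch_um = 150, depth_axis = "x"),
                   class = "ion_image")
  expect_error(depth_profile(img, window = 9), "larger than")
  expect_error(depth_profile(img, window = 2), "odd")
  expect_error(depth_profile(img, bin_um = 100), "multiple")
  # coarser bins: two raster steps per bin
  p <- depth_profile(img, bin_um = 300, window = 1)
  expect_equal(p$raw_sums, c(4, 4))
  expect_equal(p$bin_centers_um, c(150, 450))
})

test_that("depth axis y transposes the profile direction", {
  m <- matrix(0, 6, 2)
  m[, 1] <- c(1, 2, 3, 4, 5, 6)
  px <- expand.grid(x = 0:2, y = 0:1)
  px <- px[order(px$x, px$y), ]
  t0 <- msi_features(m, c(300, 400), px, depth_axis = "y")
  prof <- depth_profile(ion_image(t0, 1), window = 1)
  expect_length(prof$raw_sums, 2L)
  expect_equal(sum(prof$raw_sums), sum(m[, 1]))
})
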