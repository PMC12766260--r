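test_that("snr_filter keeps the boundary and preserves order", {
  sc <- pixel_scene(mz = c(300, 400, 500), intensity = c(1, 2, 3),
                    snr = c(3.9, 4.0, 10))
  out <- snr_filter(sc, 4)
  expect_equal(out$peaks$mz, c(400, 500))
  expect_identical(snr_filter(sc, 0)$peaks, sc$peaks)
  # empty result allowed, pixel retained
  none <- snr_filter(sc, 100)
  expect_equal(nrow(none$peaks), 0L)
  expect_equal(n_pixels(none), 1L)
})

test_that("snr_filter agrees with a brute-force count on random spectra", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    snr <- round(runif(n, 0, 8), 2)
    sc <- pixel_scene(mz = sort(150 + cumsum(runif(n, 0.01, 5))),
                      intensity = runif(n), snr = snr)
    expect_equal(nrow(snr_filter(sc, 4)$peaks), sum(snr >= 4))
  }
})

test_that("lock-mass recalibration lands the calibrant exactly", {
  sc <- pixel_scene(mz = 500.0050, intensity = 1)
  out <- lockmass_recalibrate(sc, 500.0000, search_ppm = 20)
  expect_equal(out$peaks$mz, 500.0000, tolerance = 1e-12)
  expect_equal(nrow(attr(out, "lockmass_missed")), 0L)
})

test_that("spectra without a calibrant peak are flagged and unchanged", {
  sc <- pixel_scene(mz = c(400, 600), intensity = c(1, 1))
  out <- lockmass_recalibrate(sc, 500, search_ppm = 20)
  expect_identical(out$peaks, sc$peaks)
  expect_equal(attr(out, "lockmass_missed"), data.frame(x = 0L, y = 0L))
})

test_that("a uniform scale error is removed exactly for all peaks", {
  delta <- 5e-6  # +5 ppm miscalibration
  true_mz <- c(500.0000, 823.4567)
  sc <- pixel_scene(mz = true_mz * (1 + delta), intensity = c(5, 1))
  out <- lockmass_recalibrate(sc, 500.0000, search_ppm = 20)
  expect_equal(out$peaks$mz, true_mz, tolerance = 1e-9)
})

test_that("distance ties between calibrant candidates go to the higher intensity", {
  sc <- pixel_scene(mz = c(499.9950, 500.0050), intensity = c(1, 9))
  out <- lockmass_recalibrate(sc, 500.0000, search_ppm = 20)
  # scaled on the more intense candidate at +10 ppm
  expect_equal(out$peaks$mz[2], 500.0000, tolerance = 1e-12)
})

test_that("median normalization fixes each spectrum's median at 1", {
  expect_equal(median_normalize(pixel_scene(c(300, 400, 500),
                                            c(2, 4, 6)))$peaks$intensity,
               c(0.5, 1.0, 1.5))
  expect_equal(median_normalize(pixel_scene(500, 7))$peaks$intensity, 1.0)
  # even count: median is the mean of the central pair
  expect_equal(median_normalize(pixel_scene(c(300, 400),
                                            c(1, 3)))$peaks$intensity,
               c(0.5, 1.5))
})

test_that("TIC normalization makes each spectrum sum to 1", {
  expect_equal(tic_normalize(pixel_scene(c(300, 400, 500),
                                         c(2, 4, 6)))$peaks$intensity,
               c(1 / 6, 1 / 3, 1 / 2))
  expect_equal(tic_normalize(pixel_scene(500, 3))$peaks$intensity, 1.0)
})

test_that("normalization identities hold across a whole generated scene", {
  gen <- generate_scene(make_default_scene(17L))
  sc <- snr_filter(gen$scene, 4)
  med <- suppressWarnings(median_normalize(sc))
  med_by_px <- tapply(med$peaks$intensity,
                      interaction(med$peaks$x, med$peaks$y, drop = TRUE),
                      median)
  expect_true(all(abs(med_by_px - 1) < 1e-12))
  tic <- suppressWarnings(tic_normalize(sc))
  tic_by_px <- tapply(tic$peaks$intensity,
                      interaction(tic$peaks$x, tic$peaks$y, drop = TRUE),
                      sum)
  expect_true(all(abs(tic_by_px - 1) < 1e-12))
})

test_that("pixels without peaks trigger a warning and are skipped", {
  sc <- msi_scene(data.frame(x = 0L, y = 0L, mz = 500, intensity = 2,
                             snr = 9),
                  pixels = data.frame(x = c(0L, 1L), y = c(0L, 0L)))
  expect_warning(median_normalize(sc), "no peaks")
  expect_warning(tic_normalize(sc), "no peaks")
})
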