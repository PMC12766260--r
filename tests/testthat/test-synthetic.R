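test_that("default scene configuration is deterministic and well-formed", {
  c1 <- make_default_scene(42L)
  c2 <- make_default_scene(42L)
  expect_identical(c1, c2)
  expect_false(identical(c1, make_default_scene(43L)))
  expect_gte(length(c1$components), 4L)
  ids <- vapply(c1$components, `[[`, "", "id")
  expect_setequal(ids, c("suboxic", "surface_band", "anoxic", "concretion",
                         "background"))
  # chosen defaults: 80 depth pixels x 10, 150 um pitch => 12 mm depth span
  expect_equal(c1$grid, c(80L, 10L))
  expect_equal(c1$grid[1] * c1$pixel_pitch_um, 12000)
  all_mz <- unlist(lapply(c1$components, function(cc) cc$signature$mz))
  expect_gte(min(diff(sort(c(all_mz, c1$matrix_features$mz)))), 0.1)
})

test_that("suboxic and anoxic profiles overlap over < 5% of depth bins", {
  cfg <- make_default_scene(42L)
  ids <- vapply(cfg$components, `[[`, "", "id")
  pa <- profile_matrix(cfg$components[[which(ids == "suboxic")]]$profile,
                       cfg$grid, cfg$depth_axis)
  pc <- profile_matrix(cfg$components[[which(ids == "anoxic")]]$profile,
                       cfg$grid, cfg$depth_axis)
  both <- rowMeans(pa) > 0.1 & rowMeans(pc) > 0.1
  expect_lt(mean(both), 0.05)
})

test_that("profile families stay within [0, 1] and honour their shapes", {
  grid <- c(40L, 6L)
  for (p in list(list(type = "sigmoid", center = 20, width = 1,
                      direction = "rise"),
                 list(type = "band", lo = 5, hi = 15, width = 0.5),
                 list(type = "blob", cx = 20, cy = 3, sx = 4, sy = 2),
                 list(type = "expdecay", scale = 10),
                 list(type = "constant", level = 0.7))) {
    m <- profile_matrix(p, grid)
    expect_true(all(m >= 0 & m <= 1), info = p$type)
  }
  rise <- profile_matrix(list(type = "sigmoid", center = 20, width = 1,
                              direction = "rise"), grid)
  expect_true(all(diff(rise[, 1]) >= 0))
  expect_error(profile_matrix(list(type = "nope"), grid), "unknown profile")
})

test_that("generation is bit-for-bit reproducible under a fixed seed", {
  cfg <- make_default_scene(5L)
  g1 <- generate_scene(cfg)
  g2 <- generate_scene(cfg)
  expect_identical(g1$scene$peaks, g2$scene$peaks)
  expect_identical(g1$mask$labels, g2$mask$labels)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_spectra(g1$scene, f1); write_spectra(g2$scene, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("dropout 1 silences components and zero jitter is exact", {
  cfg <- make_default_scene(3L)
  cfg$dropout_p <- 1
  cfg$matrix_features <- data.frame(mz = numeric(), abundance = numeric())
  cfg$noise_peaks_per_pixel <- 0
  g <- generate_scene(cfg)
  expect_equal(nrow(g$scene$peaks), 0L)

  cfg2 <- make_default_scene(3L)
  cfg2$mass_jitter_ppm <- 0
  cfg2$noise_peaks_per_pixel <- 0
  g2 <- generate_scene(cfg2)
  expect_true(all(g2$scene$peaks$mz %in% g2$truth$centroids))
})

test_that("signature m/z outside the analytical window is a config error", {
  cfg <- make_default_scene(3L)
  cfg$components[[1]]$signature$mz[1] <- 1200
  expect_error(generate_scene(cfg), "outside the mz window")
})

test_that("observed ppm deviations are centred on zero", {
  ppm <- unlist(lapply(c(11L, 12L), function(s) {
    cfg <- make_default_scene(s)
    cfg$noise_peaks_per_pixel <- 0  # matrix + component peaks carry jitter
    g <- generate_scene(cfg)
    pk <- g$scene$peaks
    truth <- sort(g$truth$centroids)
    idx <- findInterval(pk$mz, truth)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(truth))
    nearest <- ifelse(abs(pk$mz - truth[lo]) <= abs(pk$mz - truth[hi]),
                      truth[lo], truth[hi])
    (pk$mz - nearest) / nearest * 1e6
  }))
  expect_gt(length(ppm), 1e4)
  se <- sd(ppm) / sqrt(length(ppm))
  expect_lt(abs(mean(ppm)), 3 * se)
  expect_equal(sd(ppm), make_default_scene(11L)$mass_jitter_ppm,
               tolerance = 0.1)
})

test_that("matrix features are void-enriched by the configured factor", {
  cfg <- make_default_scene(13L)
  cfg$noise_peaks_per_pixel <- 0
  g <- generate_scene(cfg)
  lab <- g$mask$labels[cbind(g$scene$peaks$x + 1L, g$scene$peaks$y + 1L)]
  is_matrix <- sapply(g$scene$peaks$mz, function(m)
    any(abs(g$truth$matrix_mz - m) < 0.01))
  n_void <- sum(g$mask$labels == "void")
  n_sed <- sum(g$mask$labels == "sediment")
  mass_void <- sum(g$scene$peaks$intensity[is_matrix & lab == "void"]) / n_void
  mass_sed <- sum(g$scene$peaks$intensity[is_matrix & lab == "sediment"]) / n_sed
  # per-pixel expected intensity ratio ~ matrix_enrichment (stochastic)
  expect_gt(mass_void / mass_sed, cfg$matrix_enrichment / 2)
})

test_that("mean planted intensity follows the emission model over realizations", {
  # E[cell] = abundance * profile^2 * (1-dropout) * E[lognormal]:
  # average many stochastic realizations of one feature and compare
  prof <- list(type = "expdecay", scale = 8)
  base <- generator_config(
    grid = c(24L, 2L),
    components = list(component_spec("c1", data.frame(mz = 500, abundance = 2),
                                     prof)),
    matrix_features = data.frame(mz = numeric(), abundance = numeric()),
    void_blobs = list(n = 0, r_min = 1, r_max = 1),
    noise_peaks_per_pixel = 0, mass_jitter_ppm = 0, intensity_cv = 0.3,
    dropout_p = 0.2, seed = 1L)
  acc <- matrix(0, 24, 2)
  n_rep <- 150L
  for (r in seq_len(n_rep)) {
    base$seed <- r
    g <- generate_scene(base)
    pk <- g$scene$peaks
    if (nrow(pk)) acc[cbind(pk$x + 1L, pk$y + 1L)] <-
        acc[cbind(pk$x + 1L, pk$y + 1L)] + pk$intensity
  }
  mean_obs <- rowMeans(acc) / n_rep
  P <- rowMeans(profile_matrix(prof, c(24L, 2L)))
  expected <- 2 * P^2 * (1 - 0.2) * exp(0.3^2 / 2)
  expect_gt(cor(mean_obs, expected), 0.99)
  expect_equal(mean_obs, expected, tolerance = 0.15)
})
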