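# Test helpers: tiny scene builders and independent brute-force oracles.

# scene from a plain data.frame of peaks
scene_of <- function(df, mz_window = c(150, 1000), ...) {
  msi_scene(df, mz_window = mz_window, ...)
}

# one-pixel scene with given peak vectors
pixel_scene <- function(mz, intensity, snr = rep(10, length(mz)),
                        mz_window = c(150, 1000)) {
  scene_of(data.frame(x = 0L, y = 0L, mz = mz, intensity = intensity,
                      snr = snr), mz_window = mz_window)
}

# random sparse feature table on an nx x ny raster
random_table <- function(nx, ny, nf, density = 0.3, seed = 1) {
  set.seed(seed)
  px <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1))
  px <- px[order(px$x, px$y), ]
  m <- matrix(0, nrow(px), nf)
  on <- matrix(runif(length(m)) < density, nrow(m))
  m[on] <- rlnorm(sum(on))
  msi_features(m, sort(150 + cumsum(runif(nf, 0.5, 5))), px)
}

# brute-force single-linkage clustering of sorted m/z with a relative cut:
# split wherever the gap to the previous value exceeds cut_ppm of the m/z
oracle_single_linkage <- function(mzs, cut_ppm) {
  s <- sort(mzs)
  gaps <- diff(s)
  newc <- c(TRUE, gaps > cut_ppm * 1e-6 * s[-length(s)])
  cl <- cumsum(newc)
  cl[match(mzs, s)]
}

# independent re-implementation of the bin-wise KDE feature discovery
# (binning, direct Gaussian-kernel evaluation, prominence filtering,
# ownership dedup) without stats::density
oracle_kde_features <- function(mzs, mz_window, config) {
  starts <- seq(mz_window[1], mz_window[2], by = config$bin_width_da)
  if (tail(starts, 1) >= mz_window[2]) starts <- head(starts, -1L)
  found <- numeric()
  for (lo in starts) {
    hi <- min(lo + config$bin_width_da, mz_window[2])
    center <- (lo + hi) / 2
    bw <- config$kde_bandwidth_ppm * 1e-6 * center
    ext_lo <- lo - 3 * bw; ext_hi <- hi + 3 * bw
    xs <- mzs[mzs >= ext_lo & mzs <= ext_hi]
    if (!length(xs)) next
    step <- config$grid_step_ppm * 1e-6 * center
    n <- max(32L, as.integer(ceiling((ext_hi - ext_lo) / step)) + 1L)
    g <- seq(ext_lo, ext_hi, length.out = n)
    y <- vapply(g, function(p) sum(dnorm(p, xs, bw)), numeric(1))
    y <- y / max(y)
    nn <- length(y)
    cand <- which(y[2:(nn - 1)] > y[1:(nn - 2)] & y[2:(nn - 1)] >= y[3:nn]) + 1L
    for (i in cand) {
      h <- y[i]
      j <- i - 1L; lmin <- h
      while (j >= 1L && y[j] <= h) { lmin <- min(lmin, y[j]); j <- j - 1L }
      j <- i + 1L; rmin <- h
      while (j <= nn && y[j] <= h) { rmin <- min(rmin, y[j]); j <- j + 1L }
      if ((h - max(lmin, rmin)) > config$prominence_min &&
          g[i] >= lo && g[i] < hi) {
        found <- c(found, g[i])
      }
    }
  }
  sort(found)
}

# double-loop sparsity recomputation
oracle_sparsity <- function(table, zone_width) {
  d <- if (identical(table$depth_axis, "y")) table$pixels$y else table$pixels$x
  zones <- sort(unique(floor(d / zone_width)))
  frac <- matrix(0, length(zones), ncol(table$matrix))
  for (zi in seq_along(zones)) {
    rows <- which(floor(d / zone_width) == zones[zi])
    for (f in seq_len(ncol(table$matrix))) {
      frac[zi, f] <- sum(table$matrix[rows, f] > 0) / length(rows)
    }
  }
  frac
}

# brute-force centered moving average with shrinking edges
oracle_moving_average <- function(v, window) {
  h <- (window - 1) %/% 2
  sapply(seq_along(v), function(i) {
    lo <- max(1, i - h); hi <- min(length(v), i + h)
    mean(v[lo:hi])
  })
}

# scene with species planted at exact m/z values across a pixel grid
planted_species_scene <- function(species_mz, n_pixels_x, n_pixels_y,
                                  jitter_ppm, present_p = 1, seed = 1,
                                  mz_window = c(150, 1000)) {
  set.seed(seed)
  px <- expand.grid(x = 0:(n_pixels_x - 1), y = 0:(n_pixels_y - 1))
  rows <- list()
  for (m0 in species_mz) {
    on <- runif(nrow(px)) < present_p
    n <- sum(on)
    rows[[length(rows) + 1L]] <- data.frame(
      x = px$x[on], y = px$y[on],
      mz = m0 * (1 + rnorm(n, 0, jitter_ppm * 1e-6)),
      intensity = rlnorm(n), snr = 10)
  }
  scene_of(do.call(rbind, rows), mz_window = mz_window,
           pixels = px)
}
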