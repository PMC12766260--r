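#' Component specification for the synthetic scene generator
#'
#' A synthetic molecular component is a set of characteristic m/z features
#' (a signature) sharing one spatial abundance profile over the raster.
#' Profile families cover the spatial motifs of stratified sediment MSI
#' data: sharp redox-type depth transitions, thin layers, localised blobs
#' (concretions), gradual downcore decays and uniform background.
#'
#' @param id character label
#' @param signature data.frame with columns `mz` (Da) and `abundance`
#'   (positive relative weight), unique m/z
#' @param profile list describing the spatial weight function, with element
#'   `type` one of `"sigmoid"` (params `center`, `width`, `direction` =
#'   "rise"/"fall"), `"band"` (logistic-edged box: `lo`, `hi`, `width`),
#'   `"blob"` (Gaussian: `cx`, `cy`, `sx`, `sy`), `"expdecay"` (`scale`),
#'   `"constant"` (`level` in (0, 1]); depth-dependent families are
#'   functions of the depth-axis coordinate
#' @return list of class `component_spec`
#' @export
component_spec <- function(id, signature, profile) {
  signature <- as.data.frame(signature)
  stopifnot(all(c("mz", "abundance") %in% names(signature)),
            !anyDuplicated(signature$mz), all(signature$abundance > 0))
  stopifnot(is.list(profile), !is.null(profile$type))
  structure(list(id = id, signature = signature, profile = profile),
            class = "component_spec")
}

#' Evaluate a component's spatial profile over the raster
#'
#' @param profile a profile list (see [component_spec()])
#' @param grid integer `c(n_x, n_y)`
#' @param depth_axis `"x"` or `"y"`
#' @return an `n_x` by `n_y` matrix with values in `[0, 1]`
#' @export
profile_matrix <- function(profile, grid, depth_axis = "x") {
  nx <- grid[1]; ny <- grid[2]
  xs <- 0:(nx - 1); ys <- 0:(ny - 1)
  d <- if (identical(depth_axis, "y")) matrix(rep(ys, each = nx), nx, ny)
       else matrix(rep(xs, ny), nx, ny)
  p <- switch(profile$type,
    sigmoid = {
      s <- 1 / (1 + exp(-(d - profile$center) / profile$width))
      if (identical(profile$direction, "fall")) 1 - s else s
    },
    band = {
      (1 / (1 + exp(-(d - profile$lo) / profile$width))) *
        (1 / (1 + exp((d - profile$hi) / profile$width)))
    },
    blob = {
      xm <- matrix(rep(xs, ny), nx, ny)
      ym <- matrix(rep(ys, each = nx), nx, ny)
      exp(-((xm - profile$cx)^2 / (2 * profile$sx^2) +
              (ym - profile$cy)^2 / (2 * profile$sy^2)))
    },
    expdecay = exp(-d / profile$scale),
    constant = matrix(profile$level, nx, ny),
    stop("unknown profile type: ", profile$type))
  pmin(pmax(p, 0), 1)
}

#' Generator configuration
#'
#' Bundles everything [generate_scene()] needs: the raster grid, the
#' planted components, embedding-matrix features preferentially emitted in
#' void pixels, the void topology, and the noise model (ppm-scale mass
#' jitter, lognormal multiplicative intensity noise, per-pixel dropout,
#' spurious low-SNR peaks).
#'
#' @param grid integer `c(n_x, n_y)`
#' @param components list of [component_spec()]
#' @param matrix_features data.frame `mz`, `abundance`: embedding-matrix
#'   ions
#' @param matrix_p_void emission probability of a matrix feature in a void
#'   pixel
#' @param matrix_enrichment expected void/sediment emission ratio; the
#'   sediment emission probability is `matrix_p_void / matrix_enrichment`
#' @param void_blobs list `n`, `r_min`, `r_max`: number and radius range
#'   (raster units) of void blobs
#' @param mass_jitter_ppm standard deviation of the per-peak relative m/z
#'   error, in ppm
#' @param intensity_cv lognormal sigma of the multiplicative intensity
#'   noise
#' @param dropout_p probability that a present feature is missed in a pixel
#' @param noise_peaks_per_pixel Poisson mean of spurious peaks per pixel
#' @param snr_model list `real_min`, `real_meanlog`, `real_sdlog` (real
#'   peaks get SNR `real_min + LogNormal`), `noise_min`, `noise_max`
#'   (noise peaks get uniform SNR in that range)
#' @param mz_window,pixel_pitch_um,polarity,depth_axis scene metadata
#' @param seed integer controlling all randomness of the generator
#' @return list of class `generator_config`
#' @export
generator_config <- function(grid, components, matrix_features,
                             matrix_p_void = 0.9, matrix_enrichment = 10,
                             void_blobs = list(n = 6, r_min = 1, r_max = 2),
                             mass_jitter_ppm = 1.5, intensity_cv = 0.3,
                             dropout_p = 0.1, noise_peaks_per_pixel = 5,
                             snr_model = list(real_min = 4,
                                              real_meanlog = log(16),
                                              real_sdlog = 0.4,
                                              noise_min = 0.5,
                                              noise_max = 3.9),
                             mz_window = c(150, 1000), pixel_pitch_um = 150,
                             polarity = "negative", depth_axis = "x",
                             seed = 42L) {
  stopifnot(length(grid) == 2L, all(grid >= 1),
            dropout_p >= 0, dropout_p <= 1,
            matrix_p_void >= 0, matrix_p_void <= 1, matrix_enrichment >= 1,
            mass_jitter_ppm >= 0, intensity_cv >= 0,
            noise_peaks_per_pixel >= 0)
  structure(list(grid = as.integer(grid), components = components,
                 matrix_features = as.data.frame(matrix_features),
                 matrix_p_void = matrix_p_void,
                 matrix_enrichment = matrix_enrichment,
                 void_blobs = void_blobs, mass_jitter_ppm = mass_jitter_ppm,
                 intensity_cv = intensity_cv, dropout_p = dropout_p,
                 noise_peaks_per_pixel = noise_peaks_per_pixel,
                 snr_model = snr_model, mz_window = as.numeric(mz_window),
                 pixel_pitch_um = pixel_pitch_um, polarity = polarity,
                 depth_axis = depth_axis, seed = as.integer(seed)),
            class = "generator_config")
}

#' Default synthetic scene: a stratified core at desk scale
#'
#' Returns a generator configuration emulating a millimetre-scale
#' redox-stratified sediment core on an 80 (depth) x 10 raster at 150 um
#' pitch (12.0 mm of depth): (a) a suboxic component present from near the
#' surface and vanishing sharply at depth 35, (b) a thin 3-pixel band just
#' below the surface, (c) an anoxic-zone component switching on where (a)
#' ends, (d) a concretion-like Gaussian blob, and (e) a water-column-derived
#' background decaying gradually downcore; plus embedding-matrix features
#' concentrated in void pixels and spurious low-SNR noise peaks. Feature
#' m/z values are drawn once from the given seed with at least 0.1 Da
#' separation.
#'
#' @param seed integer; the same seed always yields the identical
#'   configuration
#' @return a [generator_config()]
#' @export
make_default_scene <- function(seed = 42L) {
  sizes <- c(suboxic = 10L, surface_band = 8L, anoxic = 10L,
             concretion = 8L, background = 8L)
  n_matrix <- 6L
  pool <- with_seed(seed, {
    base <- sort(sample(seq(200, 950, by = 0.5), sum(sizes) + n_matrix))
    offs <- runif(length(base), -0.2, 0.2)
    list(mz = base + offs,
         ab = runif(length(base), 0.5, 2),
         assign = sample(rep(seq_along(sizes), sizes)))
  })
  comp_mz <- pool$mz[seq_len(sum(sizes))]
  comp_ab <- pool$ab[seq_len(sum(sizes))]
  matrix_mz <- pool$mz[sum(sizes) + seq_len(n_matrix)]
  profiles <- list(
    suboxic = list(type = "band", lo = 4, hi = 35, width = 0.75),
    surface_band = list(type = "band", lo = 6.5, hi = 9.5, width = 0.3),
    anoxic = list(type = "sigmoid", center = 35, width = 0.75,
                  direction = "rise"),
    concretion = list(type = "blob", cx = 52, cy = 4.5, sx = 5, sy = 2.5),
    background = list(type = "expdecay", scale = 35))
  components <- lapply(seq_along(sizes), function(i) {
    sel <- pool$assign == i
    component_spec(names(sizes)[i],
                   data.frame(mz = comp_mz[sel], abundance = comp_ab[sel]),
                   profiles[[i]])
  })
  generator_config(grid = c(80L, 10L), components = components,
                   matrix_features = data.frame(mz = matrix_mz,
                                                abundance = 5),
                   seed = seed)
}

#' Expected component zone profiles under the generative model
#'
#' Computes, from the configuration alone, the expected zone-averaged
#' spatial profile of each planted component as the fingerprinting stage
#' sees it. For a component feature, the expected per-pixel intensity is
#' `abundance * profile^2 * (1 - dropout_p) * exp(intensity_cv^2 / 2)`
#' (emission probability times conditional mean intensity); matrix features
#' contribute their emission rate times abundance. With `tic = TRUE` the
#' expected values are divided by the pixel's expected total ion count
#' before zone averaging — total-ion-count normalization makes the data
#' compositional, and this closure visibly reshapes smooth profiles, so
#' recovery must be judged against the composition-space truth rather than
#' the absolute planted profile. Feature columns are max-scaled to [0, 1]
#' per zone matrix (mirroring [maxabs_scale()]) and averaged within each
#' component. Void placement and spurious noise peaks (removed upstream by
#' the SNR filter) are neglected.
#'
#' @param config a [generator_config()]
#' @param zone_width zone width in raster units
#' @param tic divide by the expected total ion count per pixel
#'   (default TRUE)
#' @return matrix zones x components, one column per component id
#' @export
expected_zone_profiles <- function(config, zone_width = 4L, tic = TRUE) {
  nx <- config$grid[1]; ny <- config$grid[2]
  gain <- (1 - config$dropout_p) * exp(config$intensity_cv^2 / 2)
  cols <- list(); comp_of <- character()
  for (cc in config$components) {
    P <- as.numeric(profile_matrix(cc$profile, config$grid,
                                   config$depth_axis))
    for (fi in seq_len(nrow(cc$signature))) {
      cols[[length(cols) + 1L]] <- cc$signature$abundance[fi] * P^2 * gain
      comp_of <- c(comp_of, cc$id)
    }
  }
  E <- do.call(cbind, cols)
  tic_exp <- rowSums(E)
  if (nrow(config$matrix_features)) {
    # expected matrix-ion load, void placement marginalised out
    p_void_frac <- min(1, config$void_blobs$n *
                         pi * mean(c(config$void_blobs$r_min,
                                     config$void_blobs$r_max))^2 / (nx * ny))
    rate <- config$matrix_p_void *
      (p_void_frac + (1 - p_void_frac) / config$matrix_enrichment)
    tic_exp <- tic_exp + sum(config$matrix_features$abundance) * rate *
      exp(config$intensity_cv^2 / 2)
  }
  if (tic) E <- E / tic_exp
  d <- if (identical(config$depth_axis, "y")) rep(0:(ny - 1), each = nx)
       else rep(0:(nx - 1), ny)
  zone <- floor(d / zone_width)
  Z <- apply(E, 2L, function(v) as.numeric(tapply(v, zone, mean)))
  Z <- sweep(Z, 2L, pmax(apply(Z, 2L, max), .Machine$double.xmin), "/")
  ids <- unique(comp_of)
  out <- sapply(ids, function(id) rowMeans(Z[, comp_of == id, drop = FALSE]))
  colnames(out) <- ids
  out
}

#' Generate a synthetic scene
#'
#' Realizes a [generator_config()] into a scene, a void mask and the ground
#' truth needed for recovery tests. For every pixel and every component
#' feature, a peak is emitted with probability `profile * (1 - dropout_p)`;
#' its observed m/z is the true centroid times `1 + eps` with
#' `eps ~ Normal(0, mass_jitter_ppm * 1e-6)`, its intensity is
#' `abundance * profile * LogNormal(0, intensity_cv)`, and its SNR is drawn
#' from the real-peak SNR model. Matrix features are emitted at high rate
#' in void pixels and at rate divided by `matrix_enrichment` in sediment;
#' noise peaks appear at uniform random m/z with sub-threshold SNR. Output
#' is bit-for-bit reproducible for a fixed config.
#'
#' @param config a [generator_config()]
#' @return list with `scene` ([msi_scene()]), `mask` ([void_mask()]) and
#'   `truth` (list: `profiles` — per-component spatial matrices,
#'   `membership` — data.frame `mz`, `component`, `centroids`,
#'   `matrix_mz`, `void_pixels`).
#' @export
generate_scene <- function(config) {
  nx <- config$grid[1]; ny <- config$grid[2]
  w <- config$mz_window
  all_sig <- unlist(lapply(config$components, function(cc) cc$signature$mz))
  if (length(all_sig) && (min(all_sig) < w[1] || max(all_sig) > w[2])) {
    stop("component signature m/z outside the mz window [",
         w[1], ", ", w[2], "]")
  }
  if (nrow(config$matrix_features) &&
      (min(config$matrix_features$mz) < w[1] ||
       max(config$matrix_features$mz) > w[2])) {
    stop("matrix feature m/z outside the mz window")
  }
  profs <- lapply(config$components, function(cc) {
    profile_matrix(cc$profile, config$grid, config$depth_axis)
  })
  names(profs) <- vapply(config$components, `[[`, "", "id")
  xs <- rep(0:(nx - 1), ny); ys <- rep(0:(ny - 1), each = nx)
  res <- with_seed(config$seed, {
    # void topology
    labels <- matrix("sediment", nx, ny)
    vb <- config$void_blobs
    if (vb$n > 0) for (i in seq_len(vb$n)) {
      cx <- runif(1, 0, nx - 1); cy <- runif(1, 0, ny - 1)
      r <- runif(1, vb$r_min, vb$r_max)
      hit <- (xs - cx)^2 + (ys - cy)^2 <= r^2
      labels[cbind(xs[hit] + 1L, ys[hit] + 1L)] <- "void"
    }
    is_void <- labels[cbind(xs + 1L, ys + 1L)] == "void"
    parts <- list()
    # planted component peaks
    for (ci in seq_along(config$components)) {
      cc <- config$components[[ci]]
      # voids are embedding medium: no sediment-derived signal there
      p <- as.numeric(profs[[ci]]) * !is_void
      for (fi in seq_len(nrow(cc$signature))) {
        mz0 <- cc$signature$mz[fi]; ab <- cc$signature$abundance[fi]
        emit <- runif(length(p)) < p * (1 - config$dropout_p)
        n <- sum(emit)
        if (!n) next
        parts[[length(parts) + 1L]] <- data.table(
          x = xs[emit], y = ys[emit],
          mz = mz0 * (1 + rnorm(n, 0, config$mass_jitter_ppm * 1e-6)),
          intensity = ab * p[emit] * rlnorm(n, 0, config$intensity_cv),
          snr = config$snr_model$real_min +
            rlnorm(n, config$snr_model$real_meanlog,
                   config$snr_model$real_sdlog))
      }
    }
    # matrix features, void-enriched
    if (nrow(config$matrix_features)) {
      p_pix <- ifelse(is_void, config$matrix_p_void,
                      config$matrix_p_void / config$matrix_enrichment)
      for (fi in seq_len(nrow(config$matrix_features))) {
        mz0 <- config$matrix_features$mz[fi]
        ab <- config$matrix_features$abundance[fi]
        emit <- runif(length(p_pix)) < p_pix
        n <- sum(emit)
        if (!n) next
        parts[[length(parts) + 1L]] <- data.table(
          x = xs[emit], y = ys[emit],
          mz = mz0 * (1 + rnorm(n, 0, config$mass_jitter_ppm * 1e-6)),
          intensity = ab * rlnorm(n, 0, config$intensity_cv),
          snr = config$snr_model$real_min +
            rlnorm(n, config$snr_model$real_meanlog,
                   config$snr_model$real_sdlog))
      }
    }
    # spurious low-SNR noise peaks
    if (config$noise_peaks_per_pixel > 0) {
      counts <- rpois(length(xs), config$noise_peaks_per_pixel)
      n <- sum(counts)
      if (n) {
        parts[[length(parts) + 1L]] <- data.table(
          x = rep(xs, counts), y = rep(ys, counts),
          mz = runif(n, w[1], w[2]),
          intensity = rlnorm(n, log(0.2), 0.5),
          snr = runif(n, config$snr_model$noise_min,
                      config$snr_model$noise_max))
      }
    }
    list(labels = labels, peaks = rbindlist(parts))
  })
  pk <- res$peaks
  if (!nrow(pk) || !ncol(pk)) {
    pk <- data.table(x = integer(), y = integer(), mz = numeric(),
                     intensity = numeric(), snr = numeric())
  }
  if (nrow(pk)) {
    pk <- pk[mz >= w[1] & mz <= w[2]]
    pk <- pk[, .(intensity = sum(intensity), snr = max(snr)),
             by = .(x, y, mz)]
  }
  scene <- msi_scene(pk, mz_window = w,
                     pixel_pitch_um = config$pixel_pitch_um,
                     polarity = config$polarity,
                     depth_axis = config$depth_axis,
                     pixels = data.frame(x = xs, y = ys))
  mask <- void_mask(res$labels)
  membership <- rbindlist(lapply(config$components, function(cc) {
    data.table(mz = cc$signature$mz, component = cc$id)
  }))
  truth <- list(profiles = profs,
                membership = as.data.frame(membership),
                centroids = sort(c(membership$mz, config$matrix_features$mz)),
                matrix_mz = config$matrix_features$mz,
                void_pixels = data.frame(
                  x = xs[res$labels[cbind(xs + 1L, ys + 1L)] == "void"],
                  y = ys[res$labels[cbind(xs + 1L, ys + 1L)] == "void"]))
  list(scene = scene, mask = mask, truth = truth)
}
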