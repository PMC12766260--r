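#' Alignment configuration
#'
#' Parameters for bin-wise kernel-density-estimate peak alignment. The m/z
#' axis is cut into bins of `bin_width_da`; within each bin (extended by
#' three kernel bandwidths on both sides so that features on a bin edge are
#' not split) a Gaussian KDE of all pooled peak m/z is evaluated, and its
#' prominent local maxima become consensus features.
#'
#' Bandwidth and grid step are expressed in ppm of the bin-center m/z, the
#' natural unit of mass accuracy for high-resolution MS: a 2-ppm bandwidth
#' matches the sub-2-ppm mass accuracy of FTICR peak lists, so each
#' molecular species produces a single density maximum.
#'
#' @param bin_width_da m/z partition width in Da (default 0.5)
#' @param kde_bandwidth_ppm Gaussian kernel standard deviation, as ppm of
#'   the bin center (default 2)
#' @param grid_step_ppm density evaluation grid step, ppm of the bin center
#'   (default 0.2)
#' @param prominence_min minimal prominence of a density maximum on the
#'   per-bin density curve normalized to maximum 1; maxima with prominence
#'   <= this value are discarded (default 0.01)
#' @param snr_min SNR threshold used by the preprocessing stage (default 4)
#' @return a list of class `alignment_config`
#' @export
alignment_config <- function(bin_width_da = 0.5, kde_bandwidth_ppm = 2,
                             grid_step_ppm = 0.2, prominence_min = 0.01,
                             snr_min = 4) {
  stopifnot(bin_width_da > 0, kde_bandwidth_ppm > 0, grid_step_ppm > 0,
            prominence_min > 0, prominence_min <= 1, snr_min >= 0)
  structure(list(bin_width_da = bin_width_da,
                 kde_bandwidth_ppm = kde_bandwidth_ppm,
                 grid_step_ppm = grid_step_ppm,
                 prominence_min = prominence_min, snr_min = snr_min),
            class = "alignment_config")
}

#' Bin-wise KDE peak alignment
#'
#' Pools the m/z values of all peaks in the scene, estimates their density
#' bin by bin, keeps prominent density maxima as consensus features, and
#' assigns every peak to the nearest retained maximum within three kernel
#' bandwidths. The result is a pixels-by-features intensity table; a
#' spectrum contributing several peaks to one feature has them summed.
#' Feature centroids are refined to the mean m/z of the member peaks
#' (the density maximum locates the feature; the member mean removes the
#' evaluation-grid quantization).
#'
#' Maxima found twice because bins overlap are deduplicated by keeping the
#' copy computed in the bin that owns the maximum's location. Peaks farther
#' than three bandwidths from every maximum are dropped and counted in the
#' `n_unassigned` field.
#'
#' @param scene an [msi_scene()], already SNR-filtered and normalized
#' @param config an [alignment_config()]
#' @return an [msi_features()] table with fields `support` (pixels per
#'   feature) and `n_unassigned` (dropped peaks); empty table with a warning
#'   if no density maximum survives the prominence filter.
#' @export
kde_align <- function(scene, config = alignment_config()) {
  if (!nrow(scene$peaks)) stop("kde_align: scene has no peaks")
  maxima <- kde_maxima(scene$peaks$mz, scene$mz_window, config)
  if (!nrow(maxima)) {
    warning("kde_align: no density maxima survive the prominence filter")
    return(msi_features(matrix(numeric(), n_pixels(scene), 0L), numeric(),
                        scene$pixels, scene$pixel_pitch_um, scene$depth_axis,
                        support = integer(), assign_radius_da = numeric()))
  }
  table <- project_features(scene, maxima$mz, maxima$radius_da)
  # refine centroids: mean m/z of member peaks per feature
  asg <- attr(table, "assignments")
  cent <- asg[, .(mz = mean(mz)), by = feature]
  refined <- maxima$mz
  refined[cent$feature] <- cent$mz
  ord <- order(refined)
  out <- msi_features(table$matrix[, ord, drop = FALSE], refined[ord],
                      scene$pixels, scene$pixel_pitch_um, scene$depth_axis,
                      support = table$support[ord],
                      assign_radius_da = maxima$radius_da[ord])
  out$n_unassigned <- table$n_unassigned
  out
}

# Steps: bin the m/z axis, KDE per extended bin, prominent maxima, dedup of
# maxima re-found in a neighbouring bin's overlap. A maximum belongs to the
# bin containing its location; maxima found only outside their finding
# bin's core are edge artifacts of the truncated kernel sum — except when a
# genuine maximum sits so close to a bin boundary that the phase-misaligned
# evaluation grids of the two adjacent bins place their copies on opposite
# sides of it, each disowned. Dedup therefore merges maxima closer than one
# bandwidth, keeps groups with an owned member (preferring that copy), and
# keeps an unowned group only if it lies within one grid step of a bin
# boundary. Returns data.table(mz, radius_da) sorted by mz.
kde_maxima <- function(mzs, mz_window, config) {
  starts <- seq(mz_window[1], mz_window[2], by = config$bin_width_da)
  if (tail(starts, 1) >= mz_window[2]) starts <- head(starts, -1L)
  found_mz <- numeric(); found_r <- numeric(); found_own <- logical()
  found_step <- numeric()
  mzs_sorted <- sort(mzs)
  for (lo in starts) {
    hi <- min(lo + config$bin_width_da, mz_window[2])
    center <- (lo + hi) / 2
    bw <- config$kde_bandwidth_ppm * 1e-6 * center
    ext_lo <- lo - 3 * bw; ext_hi <- hi + 3 * bw
    i0 <- findInterval(ext_lo, mzs_sorted) + 1L
    i1 <- findInterval(ext_hi, mzs_sorted)
    if (i1 < i0) next
    xs <- mzs_sorted[i0:i1]
    step <- config$grid_step_ppm * 1e-6 * center
    n <- max(32L, as.integer(ceiling((ext_hi - ext_lo) / step)) + 1L)
    d <- stats::density(xs, bw = bw, from = ext_lo, to = ext_hi, n = n)
    y <- d$y / max(d$y)
    peaks <- prominent_maxima(y, config$prominence_min)
    if (!length(peaks)) next
    px <- d$x[peaks]
    found_mz <- c(found_mz, px)
    found_r <- c(found_r, rep(3 * bw, length(px)))
    found_own <- c(found_own, px >= lo & px < hi)
    found_step <- c(found_step, rep(step, length(px)))
  }
  if (!length(found_mz)) {
    return(data.table(mz = numeric(), radius_da = numeric()))
  }
  ord <- order(found_mz)
  found_mz <- found_mz[ord]; found_r <- found_r[ord]
  found_own <- found_own[ord]; found_step <- found_step[ord]
  near_edge <- {
    b <- mz_window[1] +
      round((found_mz - mz_window[1]) / config$bin_width_da) *
        config$bin_width_da
    abs(found_mz - b) <= found_step
  }
  grp <- cumsum(c(TRUE, diff(found_mz) > found_r[-length(found_r)] / 3))
  keep <- unlist(lapply(split(seq_along(grp), grp), function(idx) {
    owned <- idx[found_own[idx]]
    if (length(owned)) return(owned[1])
    edge <- idx[near_edge[idx]]
    if (length(edge)) edge[1] else integer()
  }))
  data.table(mz = found_mz[keep], radius_da = found_r[keep])
}

# Indices of local maxima of y whose prominence exceeds prom_min.
# Prominence: height minus the higher of the two key saddles, where each
# side's saddle is the minimum of y between the peak and the nearest point
# higher than the peak (or the curve end).
prominent_maxima <- function(y, prom_min) {
  n <- length(y)
  if (n < 3L) return(integer())
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  keep <- logical(length(is_max))
  for (k in seq_along(is_max)) {
    i <- is_max[k]; h <- y[i]
    j <- i - 1L; lmin <- h
    while (j >= 1L && y[j] <= h) { lmin <- min(lmin, y[j]); j <- j - 1L }
    j <- i + 1L; rmin <- h
    while (j <= n && y[j] <= h) { rmin <- min(rmin, y[j]); j <- j + 1L }
    keep[k] <- (h - max(lmin, rmin)) > prom_min
  }
  is_max[keep]
}

#' Project a scene's peaks onto a fixed set of feature centroids
#'
#' Assigns every peak to the nearest feature centroid within that feature's
#' assignment radius (ties broken toward the lower-m/z feature) and builds
#' the pixels-by-features intensity matrix. Used internally by
#' [kde_align()], and to re-express a differently normalized copy of the
#' same scene (e.g. TIC- instead of median-normalized) on an existing
#' feature set so both tables share one zero pattern.
#'
#' @param scene an [msi_scene()]
#' @param feature_mz increasing numeric vector of feature centroid m/z
#' @param radius_da per-feature assignment radius in Da
#' @return an [msi_features()] with `support`, `n_unassigned`, and an
#'   `assignments` attribute (data.table `x`, `y`, `mz`, `intensity`,
#'   `feature`).
#' @export
project_features <- function(scene, feature_mz, radius_da) {
  stopifnot(length(feature_mz) == length(radius_da))
  pk <- scene$peaks
  k <- length(feature_mz)
  idx <- findInterval(pk$mz, feature_mz)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, k)
  dlo <- abs(pk$mz - feature_mz[lo]); dhi <- abs(pk$mz - feature_mz[hi])
  # nearest feature; exact ties go to the lower-m/z candidate
  feat <- ifelse(dlo <= dhi, lo, hi)
  dist <- pmin(dlo, dhi)
  ok <- dist <= radius_da[feat]
  asg <- data.table(x = pk$x, y = pk$y, mz = pk$mz,
                    intensity = pk$intensity, feature = feat)[ok]
  n_unassigned <- sum(!ok)
  px <- as.data.table(scene$pixels)
  px[, pixel_id := .I]
  asg <- px[asg, on = c("x", "y")]
  m <- matrix(0, nrow(px), k)
  if (nrow(asg)) {
    sums <- asg[, .(v = sum(intensity)), by = .(pixel_id, feature)]
    m[cbind(sums$pixel_id, sums$feature)] <- sums$v
  }
  support <- if (nrow(asg)) {
    tabulate(unique(asg, by = c("pixel_id", "feature"))$feature, nbins = k)
  } else integer(k)
  out <- msi_features(m, feature_mz, scene$pixels, scene$pixel_pitch_um,
                      scene$depth_axis, support = support,
                      assign_radius_da = radius_da)
  out$n_unassigned <- n_unassigned
  attr(out, "assignments") <- asg[, .(x, y, mz, intensity, feature)]
  out
}
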