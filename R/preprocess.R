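#' Filter peaks by signal-to-noise ratio
#'
#' Retains peaks whose SNR is at least `snr_min` (boundary inclusive:
#' a threshold of 4 keeps SNR = 4). Pixels losing all their peaks remain in
#' the scene's pixel list.
#'
#' @param scene an [msi_scene()]
#' @param snr_min minimum acceptable SNR (default 4, the conventional
#'   instrument-noise cut-off for FTICR imaging peak lists)
#' @return the filtered scene
#' @export
snr_filter <- function(scene, snr_min = 4) {
  stopifnot(snr_min >= 0)
  set_peaks(scene, scene$peaks[snr >= snr_min])
}

#' Lock-mass recalibration of per-pixel spectra
#'
#' For each pixel, looks for a peak within `search_ppm` of the calibrant
#' m/z; if found, the whole spectrum's m/z axis is rescaled by
#' `calibrant_mz / observed_mz`, which exactly removes a uniform relative
#' (ppm-scale) mass error. The nearest candidate wins; on an exact distance
#' tie the more intense peak is used. Pixels with no candidate peak are left
#' unchanged and reported in the `lockmass_missed` attribute.
#'
#' @param scene an [msi_scene()]
#' @param calibrant_mz theoretical m/z of the calibrant species (Da)
#' @param search_ppm half-width of the search window in ppm
#' @return the recalibrated scene, with attribute `lockmass_missed`: a
#'   data.frame of pixels where no calibrant peak was found.
#' @export
lockmass_recalibrate <- function(scene, calibrant_mz, search_ppm = 20) {
  stopifnot(search_ppm > 0, calibrant_mz > 0)
  tol_da <- search_ppm * 1e-6 * calibrant_mz
  pk <- copy(scene$peaks)
  if (nrow(pk)) {
    pk[, `:=`(mz, {
      d <- abs(mz - calibrant_mz)
      cand <- which(d <= tol_da)
      if (length(cand)) {
        pick <- cand[order(d[cand], -intensity[cand])][1]
        mz * (calibrant_mz / mz[pick])
      } else mz
    }), by = .(x, y)]
    hits <- pk[, .(hit = any(abs(mz - calibrant_mz) <= tol_da)), by = .(x, y)]
    missed <- as.data.frame(hits[hit == FALSE, .(x, y)])
  } else {
    missed <- data.frame(x = integer(), y = integer())
  }
  setorder(pk, x, y, mz)
  out <- set_peaks(scene, pk)
  attr(out, "lockmass_missed") <- missed
  out
}

#' Median normalization of per-pixel spectra
#'
#' Divides every peak intensity by the median peak intensity of its own
#' spectrum, so each spectrum's median becomes 1. Pixels without peaks are
#' skipped with a warning.
#'
#' @param scene an [msi_scene()]
#' @return the normalized scene
#' @export
median_normalize <- function(scene) {
  warn_empty_pixels(scene, "median_normalize")
  pk <- copy(scene$peaks)
  if (nrow(pk)) pk[, intensity := intensity / median(intensity), by = .(x, y)]
  set_peaks(scene, pk)
}

#' Total-ion-count normalization of per-pixel spectra
#'
#' Divides every peak intensity by the total ion count (sum of intensities)
#' of its own spectrum, so each spectrum sums to 1. Pixels without peaks, or
#' whose peaks are all zero, are skipped with a warning.
#'
#' @param scene an [msi_scene()]
#' @return the normalized scene
#' @export
tic_normalize <- function(scene) {
  warn_empty_pixels(scene, "tic_normalize")
  pk <- copy(scene$peaks)
  if (nrow(pk)) {
    zero <- pk[, .(tic = sum(intensity)), by = .(x, y)][tic == 0]
    if (nrow(zero)) {
      warning("tic_normalize: ", nrow(zero),
              " spectra with zero total intensity left unchanged")
    }
    pk[, intensity := {
      s <- sum(intensity)
      if (s > 0) intensity / s else intensity
    }, by = .(x, y)]
  }
  set_peaks(scene, pk)
}

warn_empty_pixels <- function(scene, what) {
  n_empty <- nrow(scene$pixels) - uniqueN(scene$peaks, by = c("x", "y"))
  if (n_empty > 0) {
    warning(what, ": ", n_empty, " pixels have no peaks and are skipped")
  }
  invisible(n_empty)
}
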