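#' Construct an MSI scene
#'
#' An `msi_scene` holds one imaging run: a long table of centroided peaks
#' (`x`, `y`, `mz`, `intensity`, `snr`) together with acquisition metadata.
#' Raster coordinates are 0-based integers; physical position along an axis
#' is `index * pixel_pitch_um`. One of the raster axes (default `"x"`) is the
#' depth axis of the core.
#'
#' @param peaks data.frame with columns `x`, `y`, `mz`, `intensity`, `snr`.
#'   Intensities and SNR must be non-negative, m/z within `mz_window`, and no
#'   pixel may carry two peaks at the same m/z.
#' @param mz_window numeric length-2, analytical m/z window in Da
#'   (default `c(150, 1000)`).
#' @param pixel_pitch_um physical raster spacing in micrometres (default 150).
#' @param polarity `"negative"` or `"positive"` ionisation mode.
#' @param depth_axis which raster axis increases with depth, `"x"` or `"y"`.
#' @param pixels optional data.frame of all acquired pixel coordinates
#'   (`x`, `y`); defaults to the pixels present in `peaks`. Keeping the full
#'   pixel list allows pixels that lose all peaks during filtering to remain
#'   part of the raster.
#' @return An object of class `msi_scene`.
#' @export
msi_scene <- function(peaks, mz_window = c(150, 1000), pixel_pitch_um = 150,
                      polarity = c("negative", "positive"),
                      depth_axis = c("x", "y"), pixels = NULL) {
  polarity <- match.arg(polarity)
  depth_axis <- match.arg(depth_axis)
  stopifnot(is.numeric(mz_window), length(mz_window) == 2L,
            mz_window[1] < mz_window[2], pixel_pitch_um > 0)
  pk <- as.data.table(peaks)
  req <- c("x", "y", "mz", "intensity", "snr")
  if (!all(req %in% names(pk))) {
    stop("peaks must have columns: ", paste(req, collapse = ", "))
  }
  pk <- pk[, req, with = FALSE]
  if (nrow(pk)) {
    if (any(pk$intensity < 0)) stop("negative intensities in peaks")
    if (any(pk$snr < 0)) stop("negative SNR in peaks")
    if (any(pk$mz < mz_window[1] | pk$mz > mz_window[2])) {
      stop("peak m/z outside the analytical window [",
           mz_window[1], ", ", mz_window[2], "]")
    }
    setorder(pk, x, y, mz)
    if (anyDuplicated(pk, by = c("x", "y", "mz"))) {
      stop("duplicate m/z within one pixel spectrum; collapse before construction")
    }
  }
  if (is.null(pixels)) {
    px <- unique(pk[, .(x, y)])
  } else {
    px <- unique(as.data.table(pixels)[, .(x, y)])
  }
  setorder(px, x, y)
  structure(
    list(peaks = pk, pixels = px, mz_window = as.numeric(mz_window),
         pixel_pitch_um = pixel_pitch_um, polarity = polarity,
         depth_axis = depth_axis),
    class = "msi_scene")
}

#' @export
print.msi_scene <- function(x, ...) {
  cat("msi_scene:", nrow(x$pixels), "pixels,", nrow(x$peaks), "peaks\n")
  cat("  m/z window: [", x$mz_window[1], ",", x$mz_window[2], "] Da;",
      "polarity:", x$polarity, "\n")
  cat("  pitch:", x$pixel_pitch_um, "um; depth axis:", x$depth_axis, "\n")
  invisible(x)
}

#' Number of pixels in a scene
#' @param scene an `msi_scene`
#' @return integer pixel count
#' @export
n_pixels <- function(scene) nrow(scene$pixels)

# replace the peak table, keeping metadata (internal)
set_peaks <- function(scene, peaks) {
  scene$peaks <- peaks
  scene
}

#' Construct a void mask
#'
#' A `void_mask` labels every raster cell of the measurement area as
#' `outside` (not part of the sample), `sediment`, or `void` (an
#' embedding-filled gap inside the sample, where MALDI-matrix-derived ions
#' concentrate).
#'
#' @param labels character matrix of dimension `n_x` by `n_y` with values in
#'   `c("outside", "sediment", "void")`; cell `[i, j]` labels raster
#'   coordinate `(x = i - 1, y = j - 1)`.
#' @return An object of class `void_mask`.
#' @export
void_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  ok <- labels %in% c("outside", "sediment", "void")
  if (!all(ok)) stop("mask labels must be 'outside', 'sediment' or 'void'")
  structure(list(labels = labels), class = "void_mask")
}

#' @export
print.void_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("outside", "sediment", "void")))
  cat("void_mask:", nrow(x$labels), "x", ncol(x$labels), "cells (",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

# label lookup for coordinate vectors; errors on out-of-grid coordinates
mask_labels_at <- function(mask, x, y) {
  dims <- dim(mask$labels)
  if (any(x < 0 | x >= dims[1] | y < 0 | y >= dims[2])) {
    stop("mask/table coordinate mismatch: pixel coordinates outside mask grid")
  }
  mask$labels[cbind(x + 1L, y + 1L)]
}

#' Construct a feature table
#'
#' A pixels-by-features intensity matrix produced by peak alignment. Zero
#' means "not detected in this pixel". Feature identity is the aligned
#' centroid m/z.
#'
#' @param matrix numeric matrix, pixels in rows, features in columns,
#'   non-negative.
#' @param feature_mz numeric vector of aligned centroid m/z (Da), strictly
#'   increasing, one per column.
#' @param pixels data.frame with columns `x`, `y`, one row per matrix row.
#' @param pixel_pitch_um,depth_axis acquisition metadata carried over from
#'   the scene (used by zone statistics and rendering).
#' @param support optional integer vector, pixels with a peak per feature.
#' @param assign_radius_da optional numeric vector, per-feature assignment
#'   radius in Da used during alignment (reused when projecting a
#'   differently-normalized scene onto the same features).
#' @return An object of class `msi_features`.
#' @export
msi_features <- function(matrix, feature_mz, pixels, pixel_pitch_um = 150,
                         depth_axis = "x", support = NULL,
                         assign_radius_da = NULL) {
  matrix <- as.matrix(matrix)
  feature_mz <- as.numeric(feature_mz)
  pixels <- as.data.frame(pixels)[, c("x", "y")]
  if (nrow(matrix) != nrow(pixels)) {
    stop("matrix row count must equal number of pixels")
  }
  if (ncol(matrix) != length(feature_mz)) {
    stop("matrix column count must equal number of features")
  }
  if (length(feature_mz) > 1 && any(diff(feature_mz) <= 0)) {
    stop("feature_mz must be strictly increasing")
  }
  if (length(matrix) && min(matrix) < 0) stop("feature table must be non-negative")
  colnames(matrix) <- if (length(feature_mz)) sprintf("%.4f", feature_mz)
  structure(
    list(matrix = matrix, feature_mz = feature_mz, pixels = pixels,
         pixel_pitch_um = pixel_pitch_um, depth_axis = depth_axis,
         support = support, assign_radius_da = assign_radius_da),
    class = "msi_features")
}

#' @export
print.msi_features <- function(x, ...) {
  cat("msi_features:", nrow(x$matrix), "pixels x", ncol(x$matrix),
      "features\n")
  if (length(x$feature_mz)) {
    cat("  m/z range: [", sprintf("%.4f", min(x$feature_mz)), ",",
        sprintf("%.4f", max(x$feature_mz)), "]\n")
  }
  invisible(x)
}

# depth-axis coordinate of each pixel row (internal)
depth_coord <- function(obj) {
  if (identical(obj$depth_axis, "y")) obj$pixels$y else obj$pixels$x
}

#' Subset a feature table to a set of feature m/z values
#'
#' Keeps the columns whose centroid m/z appears in `mz` (exact match),
#' preserving order and metadata. Used to carry a filtering decision made
#' on one normalization of the data over to another table on the same
#' features.
#'
#' @param table an [msi_features()]
#' @param mz numeric vector of centroid m/z values present in the table
#' @return the subset table
#' @export
subset_features_by_mz <- function(table, mz) {
  keep <- match(mz, table$feature_mz)
  if (anyNA(keep)) stop("some requested feature m/z are not in the table")
  subset_features(table, keep)
}

# subset features by column index, preserving metadata (internal)
subset_features <- function(table, keep) {
  msi_features(table$matrix[, keep, drop = FALSE], table$feature_mz[keep],
               table$pixels, table$pixel_pitch_um, table$depth_axis,
               support = table$support[keep],
               assign_radius_da = table$assign_radius_da[keep])
}
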