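#' Single-ion image
#'
#' Renders one feature of a (TIC-normalized) feature table as a per-pixel
#' intensity grid; raster cells without a spectrum (or without the feature)
#' are zero.
#'
#' @param table an [msi_features()] table
#' @param feature feature column index, or a feature m/z matched exactly
#'   against the table's 4-decimal column labels when given as character
#' @return list of class `ion_image`: `grid` (n_x by n_y matrix, cell
#'   `[i, j]` is raster coordinate `(i-1, j-1)`), `provenance`,
#'   `pixel_pitch_um`, `depth_axis`.
#' @export
ion_image <- function(table, feature) {
  j <- resolve_feature(table, feature)
  make_image(table, table$matrix[, j],
             provenance = paste0("feature ", colnames(table$matrix)[j]))
}

resolve_feature <- function(table, feature) {
  if (is.character(feature)) {
    j <- match(feature, colnames(table$matrix))
    if (is.na(j)) stop("unknown feature label: ", feature)
    return(j)
  }
  j <- as.integer(feature)
  if (is.na(j) || j < 1L || j > ncol(table$matrix)) {
    stop("unknown feature index: ", feature)
  }
  j
}

make_image <- function(table, values, provenance) {
  nx <- max(table$pixels$x) + 1L; ny <- max(table$pixels$y) + 1L
  grid <- matrix(0, nx, ny)
  grid[cbind(table$pixels$x + 1L, table$pixels$y + 1L)] <- values
  structure(list(grid = grid, provenance = provenance,
                 pixel_pitch_um = table$pixel_pitch_um,
                 depth_axis = table$depth_axis),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat("ion_image:", nrow(x$grid), "x", ncol(x$grid), "(", x$provenance, ")\n")
  invisible(x)
}

#' Weighted-average component image
#'
#' Renders the spatial distribution of one NMF component as the weighted
#' average of its features' (TIC-normalized) ion images, with weights equal
#' to the component's feature contributions raised to `power`. The fifth
#' power (default) strongly emphasises the features that dominate the
#' component's pseudo-spectrum. With `normalize = TRUE` the pixel value is
#' `sum_f w_f^power I_f(pixel) / sum_f w_f^power`; with `normalize = FALSE`
#' the unnormalized weighted sum is returned.
#'
#' @param table the TIC-normalized [msi_features()] table the model's
#'   features refer to (same columns, same order)
#' @param model a [fit_nmf()] model
#' @param component component index in `1..k`
#' @param power exponent applied to the contributions (default 5)
#' @param normalize divide by the weight sum (default TRUE)
#' @return an `ion_image`; all-zero weights give a zero image with a
#'   warning.
#' @export
component_image <- function(table, model, component, power = 5,
                            normalize = TRUE) {
  if (component < 1 || component > model$n_components) {
    stop("component index out of range: ", component)
  }
  stopifnot(power >= 1)
  if (ncol(table$matrix) != ncol(model$contributions)) {
    stop("feature table and model disagree on feature count")
  }
  w <- model$contributions[component, ]^power
  total <- sum(w)
  vals <- if (total == 0) {
    warning("component ", component, " has all-zero contributions; zero image")
    numeric(nrow(table$matrix))
  } else if (normalize) {
    # weights normalized before the product: a single non-zero weight
    # becomes exactly 1, so the image collapses to that feature's ion image
    as.numeric(table$matrix %*% (w / total))
  } else {
    as.numeric(table$matrix %*% w)
  }
  make_image(table, vals, provenance = paste0("component ", component,
                                              " (power ", power, ")"))
}

#' Depth profile of an ion image
#'
#' Sums the image over the transverse axis within consecutive depth bins of
#' `bin_um` micrometres (default one raster step, 150 um) and smooths the
#' binned sums with a centered moving average whose window shrinks at the
#' profile edges, so raw and smoothed profiles have equal length.
#'
#' @param image an `ion_image`
#' @param bin_um depth bin in micrometres; must be a positive multiple of
#'   the pixel pitch
#' @param window moving-average window in points, odd (default 5)
#' @return list of class `depth_profile`: `bin_centers_um`, `raw_sums`,
#'   `smoothed`, `window`, `bin_um`.
#' @export
depth_profile <- function(image, bin_um = image$pixel_pitch_um, window = 5L) {
  pitch <- image$pixel_pitch_um
  steps <- bin_um / pitch
  if (bin_um <= 0 || abs(steps - round(steps)) > 1e-9) {
    stop("bin_um must be a positive multiple of the pixel pitch (", pitch, " um)")
  }
  steps <- as.integer(round(steps))
  g <- image$grid
  if (identical(image$depth_axis, "y")) g <- t(g)
  per_step <- rowSums(g)  # depth runs along the rows now
  bin_idx <- (seq_along(per_step) - 1L) %/% steps
  raw <- as.numeric(tapply(per_step, bin_idx, sum))
  centers <- (sort(unique(bin_idx)) + 0.5) * bin_um
  smoothed <- moving_average(raw, window)
  structure(list(bin_centers_um = centers, raw_sums = raw,
                 smoothed = smoothed, window = as.integer(window),
                 bin_um = bin_um),
            class = "depth_profile")
}

#' Write an ion image grid as TSV
#'
#' One row per y value, one column per x value, so the file lays out like
#' the image. The numeric grid is the testable artifact; rendering to a
#' bitmap is left to the caller.
#'
#' @param image an `ion_image`
#' @param path TSV path
#' @return `path`, invisibly
#' @export
write_image_grid <- function(image, path) {
  write.table(t(image$grid), path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a depth profile as TSV
#'
#' Columns: `bin_center_um`, `raw_sum`, `smoothed`.
#'
#' @param profile a [depth_profile()]
#' @param path TSV path
#' @return `path`, invisibly
#' @export
write_depth_profile <- function(profile, path) {
  write.table(data.frame(bin_center_um = profile$bin_centers_um,
                         raw_sum = profile$raw_sums,
                         smoothed = profile$smoothed),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
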