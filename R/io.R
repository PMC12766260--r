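#' Read per-pixel spectrum exports
#'
#' Reads one or several comma-separated plain-text exports holding one peak
#' per row as `x, y, mz, intensity, snr` (a header line `x,y,mz,intensity,snr`
#' is auto-detected and skipped). Peaks outside the analytical m/z window are
#' dropped; duplicate `(x, y, mz)` rows are collapsed by summing intensity
#' and taking the maximum SNR.
#'
#' @param path_or_paths character vector of file paths; several files are
#'   concatenated into one scene.
#' @param mz_window analytical window `c(low, high)` in Da.
#' @inheritParams msi_scene
#' @return An [msi_scene()].
#' @export
read_spectra <- function(path_or_paths, mz_window = c(150, 1000),
                         pixel_pitch_um = 150,
                         polarity = c("negative", "positive"),
                         depth_axis = c("x", "y")) {
  polarity <- match.arg(polarity)
  depth_axis <- match.arg(depth_axis)
  paths <- path_or_paths
  if (!length(paths)) stop("no input files given")
  parts <- lapply(paths, read_spectra_file)
  pk <- rbindlist(parts)
  if (!nrow(pk)) stop("no peaks parsed from input: ", paste(paths, collapse = ", "))
  # full pixel set before the window cut, so windowing never deletes pixels
  px <- unique(pk[, .(x, y)])
  pk <- pk[mz >= mz_window[1] & mz <= mz_window[2]]
  # collapse duplicate (x, y, mz): sum intensity, max snr
  pk <- pk[, .(intensity = sum(intensity), snr = max(snr)), by = .(x, y, mz)]
  msi_scene(pk, mz_window = mz_window, pixel_pitch_um = pixel_pitch_um,
            polarity = polarity, depth_axis = depth_axis, pixels = px)
}

read_spectra_file <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input file: ", path)
  skip <- 0L
  first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) {
    skip <- 1L  # header line
    if (length(lines) == 1L) stop("input file holds only a header: ", path)
  }
  body <- lines[(skip + 1L):length(lines)]
  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    bad <- which(nf != 5L)[1]
    stop("malformed row in ", path, " line ", bad + skip,
         ": expected 5 comma-separated fields, got ", nf[bad])
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 5L, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1]
    stop("malformed row in ", path, " line ", bad + skip,
         ": non-numeric field")
  }
  data.table(x = as.integer(m[, 1]), y = as.integer(m[, 2]), mz = m[, 3],
             intensity = m[, 4], snr = m[, 5])
}

#' Write a scene back to a CSV spectrum export
#'
#' Inverse of [read_spectra()]; writes a header line and one
#' `x,y,mz,intensity,snr` row per peak. m/z is written at full precision so
#' a read/write round trip is lossless.
#'
#' @param scene an [msi_scene()]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_spectra <- function(scene, path) {
  pk <- scene$peaks
  lines <- c("x,y,mz,intensity,snr",
             if (nrow(pk)) sprintf("%d,%d,%.*g,%.*g,%.*g", pk$x, pk$y,
                                   17L, pk$mz, 17L, pk$intensity, 17L, pk$snr))
  writeLines(lines, path)
  invisible(path)
}

#' Derive a void mask from an image of the measurement area
#'
#' Classifies every image pixel by nearest reference colour
#' (void / sediment / outside), then block-reduces the image to the raster
#' grid by majority vote, so that each raster cell gets the label covering
#' most of its footprint.
#'
#' @param image_path PNG (or TIFF, if the `tiff` package is available) image
#'   registered to the measurement area: image column 1 corresponds to
#'   raster x = 0, image row 1 to raster y = 0.
#' @param extent integer `c(n_x, n_y)`: raster grid size the image covers.
#' @param void_color,sediment_color,outside_color reference RGB colours in
#'   `[0, 1]^3` for the three classes.
#' @return A [void_mask()] of dimension `n_x` by `n_y`.
#' @export
read_void_mask <- function(image_path, extent,
                           void_color = c(0, 0, 0),
                           sediment_color = c(0.5, 0.35, 0.2),
                           outside_color = c(1, 1, 1)) {
  img <- read_image(image_path)
  n_x <- as.integer(extent[1]); n_y <- as.integer(extent[2])
  # image stored rows = y, cols = x
  ih <- dim(img)[1]; iw <- dim(img)[2]
  if (iw < n_x || ih < n_y) {
    stop("image (", iw, " x ", ih, ") smaller than raster extent (",
         n_x, " x ", n_y, ")")
  }
  refs <- rbind(outside = outside_color, sediment = sediment_color,
                void = void_color)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  d2 <- vapply(seq_len(nrow(refs)), function(k) {
    (r - refs[k, 1])^2 + (g - refs[k, 2])^2 + (b - refs[k, 3])^2
  }, numeric(length(r)))
  cls <- max.col(-d2)  # nearest reference colour, ties to first (outside)
  cls <- matrix(cls, nrow = ih, ncol = iw)
  # block-reduce by majority vote over each cell's image footprint
  bx <- iw / n_x; by <- ih / n_y
  labels <- matrix("outside", nrow = n_x, ncol = n_y)
  lev <- rownames(refs)
  for (i in seq_len(n_x)) {
    c0 <- floor((i - 1) * bx) + 1L; c1 <- max(c0, floor(i * bx))
    for (j in seq_len(n_y)) {
      r0 <- floor((j - 1) * by) + 1L; r1 <- max(r0, floor(j * by))
      block <- cls[r0:r1, c0:c1]
      counts <- tabulate(block, nbins = 3L)
      labels[i, j] <- lev[which.max(counts)]
    }
  }
  void_mask(labels)
}

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF masks requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' Read / write a void mask as a plain-text label grid
#'
#' The grid file is a TSV of integers with one row per y value and one
#' column per x value: 0 = outside, 1 = sediment, 2 = void.
#'
#' @param path TSV file path
#' @return `read_mask_grid()` returns a [void_mask()]; `write_mask_grid()`
#'   returns `path` invisibly.
#' @export
read_mask_grid <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  if (!all(m %in% 0:2)) stop("mask grid values must be 0, 1 or 2")
  lev <- c("outside", "sediment", "void")
  void_mask(matrix(lev[t(m) + 1L], nrow = ncol(m), ncol = nrow(m)))
}

#' @rdname read_mask_grid
#' @param mask a [void_mask()]
#' @export
write_mask_grid <- function(mask, path) {
  code <- matrix(match(mask$labels, c("outside", "sediment", "void")) - 1L,
                 nrow = nrow(mask$labels))
  write.table(t(code), path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write a feature table as TSV
#'
#' Tab-separated text with a header row `x`, `y`, then one column per
#' feature labelled by its centroid m/z with fixed 4-decimal formatting,
#' and one row per pixel. `read_feature_table(write_feature_table(t))`
#' reproduces `t` within the m/z formatting precision.
#'
#' @param table an [msi_features()] table
#' @param path TSV file path
#' @param pixel_pitch_um,depth_axis metadata to attach on read (not stored
#'   in the TSV itself).
#' @return `read_feature_table()` returns an [msi_features()];
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  header <- paste(c("x", "y", colnames(table$matrix)), collapse = "\t")
  if (nrow(table$matrix)) {
    body <- apply(cbind(table$pixels$x, table$pixels$y, table$matrix), 1L,
                  function(row) paste(formatC(row, format = "g", digits = 15),
                                      collapse = "\t"))
  } else body <- character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, pixel_pitch_um = 150, depth_axis = "x") {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty feature table file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "x" || header[2] != "y") {
    stop("feature table header must start with 'x', 'y'")
  }
  feature_mz <- as.numeric(header[-(1:2)])
  if (anyNA(feature_mz)) stop("non-numeric feature m/z in header of ", path)
  nfield <- length(header)
  body <- lines[-1]
  vals <- lapply(seq_along(body), function(i) {
    f <- as.numeric(strsplit(body[i], "\t", fixed = TRUE)[[1]])
    if (length(f) != nfield) {
      stop("row ", i + 1L, " of ", path, " has ", length(f),
           " fields, header has ", nfield)
    }
    f
  })
  m <- do.call(rbind, vals)
  if (is.null(m)) m <- matrix(numeric(), 0L, nfield)
  msi_features(m[, -(1:2), drop = FALSE], feature_mz,
               data.frame(x = as.integer(m[, 1]), y = as.integer(m[, 2])),
               pixel_pitch_um = pixel_pitch_um, depth_axis = depth_axis)
}

#' Save a fingerprint model to a directory
#'
#' Writes the spatial matrix, the feature-contribution matrix, and the
#' reconstruction-error trace as TSV, plus a JSON run manifest (component
#' count, seed, iterations, convergence, per-k error trace).
#'
#' @param model a fingerprint model from [fit_nmf()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly.
#' @export
save_fingerprint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- data.frame(zone_lo = model$zone_bounds$lo, zone_hi = model$zone_bounds$hi,
                   model$spatial, check.names = FALSE)
  colnames(sp)[-(1:2)] <- paste0("component_", seq_len(model$n_components))
  write.table(sp, file.path(dir, "spatial.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  ct <- data.frame(component = seq_len(model$n_components), model$contributions,
                   check.names = FALSE)
  colnames(ct)[-1] <- sprintf("%.4f", model$feature_mz)
  write.table(ct, file.path(dir, "contributions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(data.frame(k = seq_along(model$error_trace),
                         relative_error = model$error_trace),
              file.path(dir, "error_trace.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  manifest <- list(n_components = model$n_components, seed = model$seed,
                   iterations = model$iterations, converged = model$converged,
                   final_error = model$error_trace[model$n_components],
                   error_trace = model$error_trace)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
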