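#' Per-zone sparsity of each feature
#'
#' Cuts the depth axis into zones of `zone_width` raster units (half-open
#' intervals `[k*w, (k+1)*w)` anchored at coordinate 0; a final partial zone
#' is kept if it holds at least one pixel) and computes, for every feature
#' and zone, the fraction of pixels with non-zero intensity. The summary
#' statistic per feature is the maximum fraction over zones, so a feature
#' confined to one thin layer — exactly the signal class of interest in a
#' stratified core — is scored by its density inside that layer rather than
#' diluted over the whole core.
#'
#' @param table an [msi_features()] table
#' @param zone_width zone width in raster units along the depth axis
#'   (default 30)
#' @return list of class `sparsity_report`: `fractions` (zones x features),
#'   `summary` (max fraction per feature), `zones` (data.frame `lo`, `hi`,
#'   `n_pixels`), `zone_width`.
#' @export
compute_sparsity <- function(table, zone_width = 30L) {
  stopifnot(zone_width >= 1)
  d <- depth_coord(table)
  nf <- ncol(table$matrix)
  if (!nrow(table$matrix) || !nf) {
    return(structure(list(fractions = matrix(numeric(), 0L, nf),
                          summary = numeric(nf),
                          zones = data.frame(lo = numeric(), hi = numeric(),
                                             n_pixels = integer()),
                          zone_width = zone_width),
                     class = "sparsity_report"))
  }
  zone <- floor(d / zone_width)
  zlev <- sort(unique(zone))
  frac <- matrix(0, length(zlev), nf)
  npix <- integer(length(zlev))
  nz <- table$matrix > 0
  for (z in seq_along(zlev)) {
    rows <- zone == zlev[z]
    npix[z] <- sum(rows)
    frac[z, ] <- colSums(nz[rows, , drop = FALSE]) / npix[z]
  }
  structure(list(fractions = frac,
                 summary = apply(frac, 2L, max),
                 zones = data.frame(lo = zlev * zone_width,
                                    hi = (zlev + 1) * zone_width,
                                    n_pixels = npix),
                 zone_width = zone_width),
            class = "sparsity_report")
}

#' Remove sparse features
#'
#' Drops features whose maximum per-zone non-zero fraction falls below the
#' sparsity threshold. With the default threshold of 0.07, a feature must be
#' detected in at least 7% of the pixels of some depth zone to survive.
#'
#' @param table an [msi_features()] table
#' @param report a [compute_sparsity()] report for `table`; computed on the
#'   fly if missing
#' @param threshold minimum acceptable max-zone non-zero fraction, in
#'   `[0, 1]` (default 0.07)
#' @param zone_width zone width used when `report` is missing
#' @return the filtered table (column order preserved), with attribute
#'   `sparsity_report` carrying the decision report (`retained` flag added).
#' @export
sparsity_filter <- function(table, report = NULL, threshold = 0.07,
                            zone_width = 30L) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is.null(report)) report <- compute_sparsity(table, zone_width)
  keep <- report$summary >= threshold
  report$retained <- keep
  out <- subset_features(table, which(keep))
  attr(out, "sparsity_report") <- report
  out
}

#' Exclude features concentrated in void regions
#'
#' The embedding medium filling voids inside the sample carries
#' MALDI-matrix-derived ions unrelated to the sample itself. For every
#' feature this computes the enrichment ratio
#' (mean intensity over void pixels) / (mean intensity over sediment
#' pixels); features with ratio above `ratio_max`, or detected in voids but
#' never in sediment, are excluded. Pixels labelled `outside` are ignored.
#'
#' @param table an [msi_features()] table
#' @param mask a [void_mask()] covering every pixel of `table`
#' @param ratio_max maximum acceptable void/sediment mean-intensity ratio
#'   (default 1.5)
#' @return list with `table` (filtered) and `report` (data.frame per
#'   feature: `feature_mz`, `void_mean`, `sediment_mean`, `ratio`,
#'   `excluded`).
#' @export
void_exclusion <- function(table, mask, ratio_max = 1.5) {
  stopifnot(ratio_max > 0)
  lab <- mask_labels_at(mask, table$pixels$x, table$pixels$y)
  vrows <- lab == "void"; srows <- lab == "sediment"
  if (!any(srows)) stop("void_exclusion: mask labels no sediment pixel in the table")
  if (!any(vrows)) stop("void_exclusion: mask labels no void pixel in the table")
  void_mean <- colMeans(table$matrix[vrows, , drop = FALSE])
  sed_mean <- colMeans(table$matrix[srows, , drop = FALSE])
  ratio <- ifelse(sed_mean > 0, void_mean / sed_mean,
                  ifelse(void_mean > 0, Inf, 0))
  excluded <- ratio > ratio_max
  report <- data.frame(feature_mz = table$feature_mz, void_mean = void_mean,
                       sediment_mean = sed_mean, ratio = ratio,
                       excluded = excluded, row.names = NULL)
  list(table = subset_features(table, which(!excluded)), report = report)
}
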