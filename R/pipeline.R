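#' Pipeline run configuration
#'
#' All stage parameters of an end-to-end run in one validated object. By
#' default the pipeline runs on the default synthetic scene
#' ([make_default_scene()]); pointing `spectra_csv` (and `mask_grid`) at
#' files runs on real exports instead.
#'
#' The NMF zone width defaults to 4 raster units while the sparsity zone
#' width keeps the conventional 30: zone statistics for sparsity need only
#' enough pixels per zone for a stable non-zero fraction, whereas the
#' zones-by-features matrix must still spatially resolve the stratification
#' — on the 80-unit default scene, 4-unit zones give 20 zones, the same
#' zones-per-core ratio as 30-unit zones on a centimetre-scale core raster.
#'
#' The stabilization threshold `delta_tol` likewise depends on the zone
#' matrix's size and noise level: an extra component fitted to pure noise
#' still lowers the relative error by roughly the share of residual energy
#' captured by a residual's leading singular pair, which grows as the
#' matrix shrinks. The default 0.02 sits well above that noise floor
#' (~0.01 for a 20 x 44 matrix at the default scene's zone-mean noise) and
#' well below the error drop from a genuine component (>= 0.09 on the
#' default scene); [select_n_components()] itself defaults to the
#' large-matrix value 0.0015.
#'
#' @param seed integer master seed (generator and factorization)
#' @param spectra_csv,mask_grid optional input paths; `NULL` means simulate
#' @param snr_min SNR threshold
#' @param lockmass_mz,lockmass_ppm optional lock-mass calibrant and search
#'   window; `NULL` skips recalibration
#' @param bin_width_da,kde_bandwidth_ppm,grid_step_ppm,prominence_min
#'   alignment parameters, see [alignment_config()]
#' @param sparsity_threshold,zone_width_sparsity sparsity filter parameters
#' @param void_ratio_max void/sediment enrichment exclusion threshold
#' @param zone_width_nmf zone width for [zone_average()] ahead of NMF
#' @param k_max,delta_tol,criterion component-count selection, see
#'   [select_n_components()]
#' @param power,profile_window component-image exponent and depth-profile
#'   smoothing window
#' @return list of class `msi_run_config`
#' @export
msi_run_config <- function(seed = 42L, spectra_csv = NULL, mask_grid = NULL,
                           snr_min = 4, lockmass_mz = NULL, lockmass_ppm = 20,
                           bin_width_da = 0.5, kde_bandwidth_ppm = 2,
                           grid_step_ppm = 0.2, prominence_min = 0.01,
                           sparsity_threshold = 0.07,
                           zone_width_sparsity = 30L, void_ratio_max = 1.5,
                           zone_width_nmf = 4L, k_max = 8L,
                           delta_tol = 0.02, criterion = "decrement",
                           power = 5, profile_window = 5L) {
  cfg <- list(seed = as.integer(seed), spectra_csv = spectra_csv,
              mask_grid = mask_grid, snr_min = snr_min,
              lockmass_mz = lockmass_mz, lockmass_ppm = lockmass_ppm,
              bin_width_da = bin_width_da,
              kde_bandwidth_ppm = kde_bandwidth_ppm,
              grid_step_ppm = grid_step_ppm, prominence_min = prominence_min,
              sparsity_threshold = sparsity_threshold,
              zone_width_sparsity = as.integer(zone_width_sparsity),
              void_ratio_max = void_ratio_max,
              zone_width_nmf = as.integer(zone_width_nmf),
              k_max = as.integer(k_max), delta_tol = delta_tol,
              criterion = criterion, power = power,
              profile_window = as.integer(profile_window))
  structure(cfg, class = "msi_run_config")
}

#' Save / load a run configuration
#'
#' Flat JSON serialization; loading rejects unknown keys and reproduces the
#' saved configuration exactly.
#'
#' @param config an [msi_run_config()]
#' @param path JSON file path
#' @return `save_run_config()` returns `path` invisibly;
#'   `load_run_config()` returns the configuration.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(msi_run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(msi_run_config, raw)
}

#' Run the full fingerprinting pipeline
#'
#' Executes simulate (or read) -> SNR filter -> optional lock-mass
#' recalibration -> median normalization -> KDE alignment -> sparsity
#' filter -> void exclusion -> TIC-normalized zone averaging -> max-abs
#' scaling -> component-count selection -> NMF -> component images and
#' depth profiles, writing every intermediate artifact plus a JSON run
#' manifest into `out_dir`. Any stage failure aborts with an error naming
#' the stage; the manifest records whatever stages completed.
#'
#' @param config an [msi_run_config()]
#' @param out_dir output directory, created if missing
#' @return the run manifest, invisibly (also written as `manifest.json`):
#'   parameter echo, per-stage counts, selected k, final error, seed and
#'   timestamps.
#' @export
run_msi_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "msi_run_config"))
  # pre-flight: inputs must exist before anything is computed or written
  for (p in c(config$spectra_csv, config$mask_grid)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("pipeline pre-flight: input does not exist: ", p)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = unclass(config),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list(), seed = config$seed)
  finish <- function(m) {
    m$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    m
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(failed = conditionMessage(e))
      finish(manifest)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- input stage: simulate or read --------------------------------------
  inp <- run_stage("input", {
    if (is.null(config$spectra_csv)) {
      gen <- generate_scene(make_default_scene(config$seed))
      write_spectra(gen$scene, file.path(out_dir, "spectra.csv"))
      write_mask_grid(gen$mask, file.path(out_dir, "mask.tsv"))
      jsonlite::write_json(
        list(membership = gen$truth$membership,
             centroids = gen$truth$centroids,
             matrix_mz = gen$truth$matrix_mz),
        file.path(out_dir, "ground_truth.json"), digits = NA, pretty = TRUE)
      gen
    } else {
      scene <- read_spectra(config$spectra_csv)
      mask <- if (!is.null(config$mask_grid)) read_mask_grid(config$mask_grid)
      list(scene = scene, mask = mask, truth = NULL)
    }
  })
  manifest$stages$input <- list(n_spectra = n_pixels(inp$scene),
                                n_peaks = nrow(inp$scene$peaks),
                                synthetic = is.null(config$spectra_csv))

  # -- preprocessing ------------------------------------------------------
  pp <- run_stage("preprocess", {
    sc <- snr_filter(inp$scene, config$snr_min)
    n_snr <- nrow(sc$peaks)
    if (!is.null(config$lockmass_mz)) {
      sc <- lockmass_recalibrate(sc, config$lockmass_mz, config$lockmass_ppm)
    }
    acfg <- alignment_config(config$bin_width_da, config$kde_bandwidth_ppm,
                             config$grid_step_ppm, config$prominence_min,
                             config$snr_min)
    med <- suppressWarnings(median_normalize(sc))
    feats <- kde_align(med, acfg)
    tic <- suppressWarnings(tic_normalize(sc))
    tic_feats <- project_features(tic, feats$feature_mz,
                                  feats$assign_radius_da)
    write_feature_table(feats, file.path(out_dir, "features.tsv"))
    list(feats = feats, tic_feats = tic_feats, n_snr = n_snr)
  })
  manifest$stages$preprocess <- list(
    n_peaks_after_snr = pp$n_snr,
    n_peaks_dropped_by_snr = nrow(inp$scene$peaks) - pp$n_snr,
    n_features_aligned = ncol(pp$feats$matrix),
    n_peaks_unassigned = pp$feats$n_unassigned)

  # -- feature filtering --------------------------------------------------
  fl <- run_stage("filter", {
    sp <- sparsity_filter(pp$feats, threshold = config$sparsity_threshold,
                          zone_width = config$zone_width_sparsity)
    if (!is.null(inp$mask)) {
      ve <- void_exclusion(sp, inp$mask, config$void_ratio_max)
      tab <- ve$table
      write.table(ve$report, file.path(out_dir, "void_report.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    } else {
      ve <- NULL; tab <- sp
    }
    tic_tab <- subset_features_by_mz(pp$tic_feats, tab$feature_mz)
    write_feature_table(tab, file.path(out_dir, "features_filtered.tsv"))
    write_feature_table(tic_tab, file.path(out_dir, "features_filtered_tic.tsv"))
    list(tab = tab, tic_tab = tic_tab, n_sparsity = ncol(sp$matrix))
  })
  manifest$stages$filter <- list(
    n_features_after_sparsity = fl$n_sparsity,
    n_features_after_void = ncol(fl$tab$matrix))

  # -- fingerprinting -----------------------------------------------------
  fp <- run_stage("fingerprint", {
    zm <- zone_average(fl$tic_tab, config$zone_width_nmf)
    sc <- maxabs_scale(zm)
    sel <- select_n_components(sc$zm, k_max = config$k_max,
                               delta_tol = config$delta_tol,
                               seed = config$seed,
                               criterion = config$criterion)
    model <- fit_nmf(sc$zm, sel$k, seed = config$seed)
    save_fingerprint(model, file.path(out_dir, "fingerprint"))
    list(model = model, sel = sel)
  })
  manifest$stages$fingerprint <- list(
    k_selected = fp$sel$k, stabilized = fp$sel$stabilized,
    final_error = fp$model$error_trace[fp$model$n_components],
    error_trace = fp$model$error_trace)

  # -- rendering ----------------------------------------------------------
  run_stage("render", {
    for (k in seq_len(fp$model$n_components)) {
      img <- component_image(fl$tic_tab, fp$model, k, power = config$power)
      write_image_grid(img, file.path(out_dir,
                                      sprintf("component_%02d_image.tsv", k)))
      prof <- depth_profile(img, window = config$profile_window)
      write_depth_profile(prof, file.path(out_dir,
                                          sprintf("component_%02d_profile.tsv", k)))
    }
    NULL
  })
  manifest$stages$render <- list(n_images = fp$model$n_components)

  invisible(finish(manifest))
}
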