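Package: msifinger
Title: Untargeted Molecular Fingerprinting of Mass Spectrometry Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An untargeted data-mining pipeline for matrix-assisted laser
    desorption ionisation mass spectrometry imaging (MALDI-MSI) of stratified
    environmental samples such as sediment cores. Reads per-pixel centroided
    peak exports (m/z, intensity, signal-to-noise), performs signal-to-noise
    filtering, lock-mass recalibration, median and total-ion-count
    normalization, and bin-wise kernel-density-estimate peak alignment into a
    pixels-by-features table. Sparse features and embedding-matrix-derived
    features are removed using spatial zone statistics and a void mask.
    Zone-averaged, max-abs-scaled data are factorized by non-negative matrix
    factorization into spatial molecular fingerprints and pseudo-spectra,
    with component-count selection by reconstruction-error stabilization.
    Renders single-ion images, contribution-weighted component images and
    smoothed depth profiles, and includes a synthetic-scene generator with
    planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
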