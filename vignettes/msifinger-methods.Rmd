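---
title: "Molecular fingerprinting of stratified MSI data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular fingerprinting of stratified MSI data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msifinger)
```

## The problem

MALDI mass spectrometry imaging of sediment cores and similar stratified
samples yields one centroided mass spectrum per raster pixel — tens of
thousands of (m/z, intensity, SNR) triplets per measurement region. The
scientific signal of interest is millimetre-scale *stratification*: groups
of molecular features (lipids and other biomarkers) that co-occur in a
depth horizon because the organisms or processes producing them are
confined to that horizon. Between the raw per-pixel peak lists and such
"molecular fingerprints" stand several data-mining steps, each of which
this package implements as a separately testable operation:

1. **SNR filtering** — peaks with signal-to-noise below a threshold
   (default 4, boundary inclusive) are treated as instrument noise.
2. **Lock-mass recalibration** — if a known calibrant species is found
   within a ppm search window, the spectrum's m/z axis is rescaled
   multiplicatively so the calibrant lands exactly on its theoretical
   mass. A multiplicative correction removes a *uniform relative* mass
   error exactly, which is the dominant error mode of FTICR calibration
   drift; spectra without a calibrant peak are flagged, not guessed at.
3. **Median normalization** — each spectrum is divided by its median peak
   intensity, equalizing per-pixel signal level ahead of alignment and
   sparsity statistics.
4. **KDE peak alignment** — peak m/z values from *all* pixels are pooled,
   and maxima of their kernel density estimate become consensus features
   (next section).
5. **Sparsity filtering and void exclusion** — features detected in too
   few pixels of every depth zone, or concentrated in embedding-filled
   voids, are removed.
6. **NMF fingerprinting** — the TIC-normalized, zone-averaged,
   max-abs-scaled feature table is factorized into non-negative spatial
   fingerprints and pseudo-spectra.
7. **Rendering** — single-ion images, contribution-weighted component
   images and smoothed depth profiles.

## KDE peak alignment

All pooled m/z values are partitioned into bins of `bin_width_da`
(default 0.5 Da). Each bin is extended by three kernel bandwidths on both
sides, so a feature sitting on a bin edge is seen whole by at least one
bin. Within each extended bin a Gaussian KDE is evaluated on a grid of
`grid_step_ppm` (default 0.2 ppm of the bin center); local maxima of the
density, normalized per bin to maximum 1, are retained when their
topographic prominence exceeds `prominence_min` (default 0.01). Every
peak is then assigned to the nearest retained maximum within three
bandwidths (ties toward the lower m/z); unassigned peaks are dropped and
counted. The feature's reported centroid is the mean m/z of its member
peaks — the density maximum locates the feature, but the member mean
removes the evaluation-grid quantization, so a zero-jitter species is
centred exactly.

Bandwidth (`kde_bandwidth_ppm`, default 2) is expressed in ppm because
mass error of high-resolution instruments is relative. The default suits
sub-2-ppm FTICR peak lists; for data with larger mass error the bandwidth
should be raised to match it, since the 3-bandwidth assignment radius
must cover the jitter distribution (at 3 ppm jitter and 2 ppm bandwidth,
the radius is only two standard deviations and several percent of
genuine peaks would go unassigned).

Maxima re-found in two neighbouring bins' overlap are deduplicated by
ownership: a maximum belongs to the bin containing its location. Two
subtleties required care. First, the evaluation grids of adjacent bins
are phase-misaligned, so a maximum lying essentially *on* a bin boundary
can be placed on opposite sides of it by the two grids and disowned by
both; such groups are kept when they lie within one grid step of a
boundary. Second, a bin's extension sees only a truncated view of a
cluster belonging to its neighbour, which can produce a spurious edge
maximum there; unowned maxima away from a boundary are therefore
discarded.

## Two normalizations, one zero pattern

Median-normalized intensities feed alignment and the sparsity filter;
TIC-normalized intensities (each spectrum divided by its total ion count)
feed zone averaging, factorization and images. Whether these should be
one operation or two is genuinely open; the package provides both and
wires them as above by default. To keep the two views consistent, the
TIC-normalized table is built by *projecting* the TIC-normalized peaks
onto the feature set discovered on the median-normalized data
(`project_features()`), so both tables share one assignment and one zero
pattern, and a filtering decision made on one carries over to the other
by column subsetting.

## Sparsity and void filtering

Sparsity is computed per depth zone: the depth axis is cut into
half-open zones of `zone_width` raster units (default 30, anchored at
coordinate 0, partial last zone kept), and for each feature and zone the
fraction of pixels with non-zero intensity is recorded. The retention
summary is the **maximum fraction over zones**: a feature confined to one
thin horizon — precisely the signal class stratification studies are
after — is scored by its density inside that horizon, whereas a global
non-zero fraction would discard it. The default threshold is 7%.

Voids are gaps in the sample filled by embedding medium and coated with
MALDI matrix; ions concentrated there are matrix-derived, not
sample-derived. "Disproportionately concentrated" is operationalized as
the ratio of mean intensity over void pixels to mean intensity over
sediment pixels exceeding `ratio_max` (default 1.5); features detected in
voids but never in sediment are excluded outright, and `outside` pixels
are ignored. Because the filters' statistics are computed on the
unfiltered table, sparsity filtering and void exclusion commute.

## NMF fingerprinting

The TIC-normalized table is averaged over depth zones (zeros included),
each feature column is scaled to [0, 1] by its maximum, and the
zones-by-features matrix X is factorized as X ≈ WH with W (zones ×
k) ≥ 0 the spatial fingerprints and H (k × features) ≥ 0 the
pseudo-spectra, minimizing the relative Frobenius error ‖X − WH‖F/‖X‖F.

The solver is hierarchical alternating least squares (HALS) with momentum
extrapolation and restart, started from a deterministic NNDSVD
initialization (the seed only perturbs exactly-zero initial entries).
Plain alternating updates have a slow linear tail on near-exact-rank
problems — on an exact rank-3 test matrix they plateau near 1e-4 relative
error after 500 sweeps — while the extrapolated variant reaches below
1e-9 within ~200 iterations. Convergence is declared when the error
change per iteration falls below `tol` (default 1e-9; a change tolerance
must sit well below the error scale one wants to resolve) or at
`max_iter` (default 500, flagged by a warning).

Models for k = 1, 2, … are fitted as a warm-started chain: the (k+1)-model
starts from the k-model plus one component seeded from the non-negative
part of the residual (a plain NNDSVD start and a vanishing-new-component
start are also tried, and the best final fit kept). This makes the error
trace non-increasing in k by construction and every reported model
reproducible bit-for-bit from its seed.

**Component-count selection.** The selected k is the smallest one whose
error *decrement*, err(k) − err(k+1), falls below `delta_tol` — the point
where the trace has stabilised. An absolute reading (smallest k with
err(k) < `delta_tol`) is available via `criterion = "absolute"`; an
absolute error floor is data-scale-dependent and rarely attainable on
noisy data, so the decrement reading is the default. The stabilization
threshold itself scales with the problem: fitting one extra component to
pure noise still captures roughly the leading singular pair's share of
the residual energy, which grows as the matrix shrinks. For a large
zone matrix (tens of zones × thousands of features) 0.0015 is apt and is
the `select_n_components()` default; for the 20 × 44 default synthetic
scene the noise-driven decrement floor is ≈ 0.01 while a genuine
component drops the error by ≥ 0.09, so the pipeline configuration
defaults to `delta_tol = 0.02`, comfortably inside that gap.

## Rendering

A component image is the weighted average of its features' TIC-normalized
ion images, the weights being the component's contributions raised to the
fifth power (default) to emphasise dominant features. The weighted sum is
normalized by the weight total (weights are normalized before the matrix
product, so a component with a single non-zero contribution reproduces
that feature's ion image exactly); the unnormalized sum is available by
flag, since the normalization convention is a rendering choice, not a
property of the data. Component images are invariant to rescaling a
component's contribution vector.

Depth profiles sum an image over the transverse axis in bins of `bin_um`
(default one raster step, 150 μm) and smooth with a centered moving
average (default 5 points) whose window shrinks at the edges, keeping the
profile length equal to the bin count and the raw sums' total exactly
equal to the image total.

## The synthetic scene generator

`make_default_scene()` encodes the study conditions used throughout the
tests: an 80 (depth) × 10 pixel raster at 150 μm pitch — 12.0 mm of
depth — with five planted components chosen to cover the spatial motifs
of redox-stratified hydrothermal sediment:

* **suboxic** — present from near-surface, vanishing sharply at depth 35
  (logistic edges, width 0.75 pixels);
* **surface_band** — a thin ~3-pixel band just below the surface;
* **anoxic** — switching on where the suboxic component ends (the two
  overlap over < 5% of depth bins);
* **concretion** — a Gaussian blob (σ 5 × 2.5 pixels) centred at depth 52;
* **background** — a water-column-derived signal decaying exponentially
  downcore (scale 35 pixels).

Each component carries 8–10 characteristic m/z features drawn once per
seed from 200–950 Da with ≥ 0.1 Da separation. A peak of feature f of
component c is emitted in a pixel with probability
profile × (1 − dropout), with observed m/z = true m/z × (1 + ε),
ε ~ N(0, 1.5 ppm), and intensity = abundance × profile × LogNormal(0,
0.3) — so the *expected* cell intensity is proportional to profile².
Six embedding-matrix features are emitted at rate 0.9 in void pixels and
10× less in sediment; component peaks are emitted only in sediment
pixels, because voids are embedding medium and physically carry no
sediment signal (this is also the premise that makes void-based exclusion
valid at all). Spurious noise peaks (Poisson mean 5 per pixel) appear at
uniform m/z with SNR drawn below 4, while genuine peaks draw SNR above 4,
so the SNR filter removes exactly the planted noise under default
settings — both SNR models are configurable to exercise the filter.
Noise levels (CV 0.3, dropout 0.1, jitter 1.5 ppm) were chosen once as
realistic for matrix-assisted ionisation of complex samples on an FTICR
instrument.

All randomness flows from a single integer seed through one RNG stream in
a fixed draw order, so generation is bit-for-bit reproducible.

**What the generator does not emulate.** Isotope patterns, ion
suppression, chemical (structured) noise spectra, spatial drift of the
calibration, and the compositional correlation structure of real lipid
extracts. Passing recovery tests on this generator therefore shows the
*pipeline machinery* is correct — alignment separates what jitter allows,
filters remove what they are defined to remove, the factorization finds
planted low-rank spatial structure — not that real sediment data will be
as clean.

**TIC closure and the recovery reference.** Dividing each spectrum by its
total ion count makes the data compositional: a feature's TIC-normalized
profile is its absolute profile reshaped by the varying total signal. On
the default scene the smooth background component's composition-space
profile correlates only r ≈ 0.87 with its absolute planted profile, so no
factorization of TIC-normalized data could reach r ≥ 0.9 against the
absolute truth. Recovery is therefore assessed against
`expected_zone_profiles()`, the expected TIC-space zone profile computed
from the generator configuration alone (profile², dropout, lognormal mean
and expected TIC; void placement and SNR-filtered noise neglected) —
independent of any realized dataset. On the default scene at seed 42 the
pipeline selects k = 5 and matches all five components at r ≥ 0.94, with
the top contributing features recovering the planted signatures in full.

## Problem sizes and determinism

The default test and acceptance runs use the 800-pixel scene
(~14,000 peaks), a 20 × 44 zone matrix and k ≤ 8; a full pipeline run
takes a few seconds. The whole pipeline is deterministic given the run
configuration: two runs with the same seed produce byte-identical numeric
artifacts, and the run manifest differs only in timestamps.

## Known limitations

* Per-window analysis only: datasets from different acquisition windows
  are processed as separate runs and merged, if desired, by feature-table
  column concatenation; no joint factorization across runs or polarities.
* Inputs must be centroided; no profile-mode peak picking, isotope
  deconvolution, or inter-run drift correction beyond the single lock
  mass.
* The void rule is a fixed ratio threshold, not a statistical test; the
  sparsity rule's max-over-zones summary is an interpretation of an
  ambiguous convention (documented above) and can be replaced by the
  caller by filtering on `compute_sparsity()` output directly.
* Exhaustive component matching in `match_components()` is limited to
  8 components.
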