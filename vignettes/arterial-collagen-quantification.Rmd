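---
title: "Quantifying arterial collagen from contrast-enhanced micro-CT and histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying arterial collagen from contrast-enhanced micro-CT and histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arteryct)
```

## The measurement model

`arteryct` quantifies collagen in the arterial wall from two modalities that
observe the same tissue:

* **Contrast-enhanced micro-CT.** A phosphotungstic-acid (PTA) stain binds
  preferentially to collagen, so X-ray attenuation — expressed in Hounsfield
  Units after the affine rescale `HU = stored_pixel × slope + intercept`
  read from the DICOM headers — carries a collagen signal. The package
  treats this rescale as definitional: whether a particular scanner exports
  calibrated HU or vendor-scaled values is a property of the acquisition,
  not of the analysis.
* **Picrosirius-red histology under polarized light.** Birefringent
  collagen appears bright under crossed polarizers; because fibres at the
  extinction angle go dark, two images 90° apart are combined (pixelwise
  maximum) so that every collagen pixel is visible in at least one. The
  collagen content of a section is a pure pixel ratio: white pixels of the
  binarized combined PLM image, intersected with the binarized brightfield
  tissue mask, divided by white pixels of the brightfield image, inside a
  region of interest. Intersecting the numerator with the tissue mask is
  what guarantees the statistic stays in [0, 1].

The cross-modality question is whether HU predicts collagen content across
samples. A confound intervenes: with a fixed staining protocol, larger
samples dilute the available stain, depressing HU independently of
collagen. The pipeline therefore applies a cohort-relative correction:
every tissue volume is divided by the *smallest* tissue volume in the
cohort, giving a normalizing ratio ≥ 1 (exactly 1 for the smallest
sample), and mean HU is multiplied by this ratio before the Pearson
correlation is computed. Multiplying an attenuation value by a relative
volume has no physical derivation — it is a first-order empirical
correction, applied exactly as stated, and the package reports both raw and
normalized correlations so the effect of the step is always visible.

## Pipeline stages and their parameters

### HU conversion and I/O

`read_dicom_series()` accepts a directory of single-frame, uncompressed,
explicit-VR little-endian slices, orders them by the z component of
ImagePositionPatient (falling back to SliceLocation, then InstanceNumber —
file names are never trusted), and refuses series with inconsistent slice
shapes. Missing rescale metadata degrades to slope 1 / intercept 0 with a
warning rather than an error, because unscaled stored pixels are still
analysable. All internal geometry is in micrometres; arrays use index order
(slice, row, column), 1-based, fixed once so ROI placement is unambiguous.
A raw-volume + JSON sidecar format (`write_ct_sidecar()`) serves as a
lighter interchange container.

### Layer segmentation

Per-layer HU intervals are **half-open** `[low, high)`: a value exactly at
a shared boundary belongs to the upper interval, a deterministic rule in
place of an unspecified tie convention. Where intervals overlap, a fixed
priority resolves the conflict — adventitia > media > intima > lumen by
default, i.e. the more densely staining layer wins; the order is
configurable. Voxels falling in no interval are background.

The shipped `default_layer_thresholds()` derive interval boundaries from
the phantom's layer HU bands (midpoints between adjacent bands, with the
media band spanning its collagen gradient). They are deliberately marked
*uncalibrated*: thresholds for real acquisitions depend on stain
concentration, staining time and scanner settings, and must be established
per protocol.

`grow_region()` is a seeded flood fill over the in-interval voxel set,
implemented in C++; connectivity defaults to 6 (faces only) because
conservative growth leaks less through noise bridges, with 26 available. An
optional `majority_filter()` (3×3×3 mode, ties keeping the centre label)
stands in for the manual cleanup an interactive workflow would apply — it
is off by default precisely because it is a modelling choice, not part of
the core definition.

### Media ROI statistics

The sampling protocol mirrors a manual workflow: three disc ROIs in the
internal media and three in the external media, on each of three slices,
averaged into one grand mean per region (mean of the 9 ROI means; every raw
ROI mean is retained for audit). Counts are configurable; deviations raise
a protocol error rather than silently computing something else.

Two conventions had to be fixed where common practice is silent:

* **Disc membership** is pixel-centre distance *strictly less than* the
  radius — the simplest deterministic rasterization.
* **Internal vs external media** is operationalized as the inner and outer
  radial *thirds* of the media band (automatic placement targets the radial
  midpoint of each third). The boundary between "internal" and "external"
  media is nowhere defined anatomically; a third-based split is symmetric
  and auditable.

`line_profile()` samples HU along a segment by bilinear interpolation
(profiles are continuous curves, so nearest-neighbour staircase artefacts
are avoided), reporting positions in micrometres. `window_level()` is the
standard display mapping with round-half-up as the tie rule, so display
output is bit-reproducible; it is never used in quantification.

### Histology

Binarization defaults to Otsu's threshold, computed by an exhaustive sweep
over the image's distinct intensities for the maximal between-class
variance — parameter-free, reproducible, and exact on the two-valued images
the synthetic sections produce; a fixed threshold (`image >= t`) is
available where Otsu's bimodality assumption fails (the degenerate
single-intensity case raises an error advising exactly that). The
white-on-dark polarity convention is declared in the image manifest;
brightfield slides with dark tissue on a bright background are inverted on
load.

## The synthetic phantoms

The generator exists so that every stage has exact ground truth. Its
defaults are the package's statement of the study conditions it emulates:

* **Geometry**: a layered cylinder (lumen / intima / media / adventitia on
  an ethanol background) at 6 µm isotropic voxels — the resolution scale of
  high-resolution specimen scans. The default grid (16 × 96 × 96) holds a
  vessel scaled down from real carotid dimensions so that a full phantom
  remains a sub-second object; geometry, not size, is what downstream code
  depends on.
* **Attenuation**: per-voxel noiseless HU is
  `layer_mean_hu[layer] + hu_per_collagen × collagen`, with the collagen
  fraction interpolating *linearly in radius* across the media between an
  internal and an external value (default 0.2 → 0.6) — the simplest model
  consistent with a collagen-rich external media — and zero elsewhere.
  Defaults put the layers at background 200, lumen 1 000, intima 2 500,
  media 4 000 (+ 5 000 × collagen), adventitia 9 000 HU: distinct,
  separable bands with the ethanol background far below stained tissue.
* **Acquisition surrogates**: Gaussian blur (default σ = 0.5 voxels) as a
  partial-volume stand-in is applied *before* additive Gaussian noise
  (default σ = 80 HU, 10 % of the smallest inter-band gap), because partial
  volume is an acquisition effect that precedes detector noise. Stored
  pixels are `round((HU − intercept)/slope)` clipped to unsigned 16-bit,
  matching CT stored-pixel conventions (defaults slope 0.25,
  intercept −1 000, so the conversion is exercised non-trivially).
* **Histology**: collagen pixels are drawn per pixel by seeded Bernoulli
  sampling at the planted fraction and split exclusively between the two
  PLM angles — only the *area fraction* enters the statistic, so no fibre
  texture is synthesized. Brightfield tissue is a flat bright level on a
  dark background.
* **Cohorts**: `generate_cohort()` scales all radii and the imaged slab
  length by the cube root of a volume multiplier (so voxel-counted tissue
  volume scales by the multiplier) and centres the media gradient on a
  per-sample collagen level (± 0.1 by default). The record-level
  `simulate_cohort_records()` adds the stain-dilution confound: the
  stain-driven HU above a native-tissue baseline (600 HU) is divided by the
  sample's relative volume, collagen levels are spread over [0.2, 0.8],
  volumes are uniform on [1, 2.5] × 2 mm³, with 150 HU of ROI noise and
  0.02 of histological measurement noise — a six-sample design matching the
  scale of the study this emulates.

What the phantoms do **not** emulate: X-ray physics (beam hardening, energy
dependence), stain diffusion kinetics, fibre orientation and texture,
histological processing artefacts (wrinkling, tearing, compression), or
slide-to-scan registration. Passing tests therefore demonstrate that the
*quantification chain* is correct — conversions, conventions, statistics —
not that any particular threshold set or staining protocol is valid on real
tissue.

## Numerical choices, in one place

* Half-open HU intervals; boundary values go to the upper interval.
* Overlap priority adventitia > media > intima > lumen (configurable).
* Region growing: 6-connectivity default; the grown mask is always a
  connected subset of the thresholded set.
* Majority filter ties keep the centre voxel's label.
* Disc ROIs: pixel-centre distance < radius; discs must lie fully inside
  the slice.
* Window/level rounds half-up; `hu = level` maps to 128.
* Otsu by exhaustive sweep over distinct intensities (no histogram
  binning); foreground is `image >= threshold`.
* Stored pixels round to nearest integer, clipped to [0, 65535].
* All seeded randomness runs under a locally set RNG state that restores
  the caller's `.Random.seed`.

Degenerate inputs are errors with typed condition classes rather than
silent defaults: zero rescale slope, constant images under Otsu, ROIs
without tissue, zero-variance or n < 3 correlations, non-positive tissue
volumes, unpaired samples, seeds outside the growing interval.

## Validation scales

The test suite and `scripts/acceptance.R` exercise the pipeline at sizes
chosen to make the statistics sharp while keeping a full run inside a
coffee break on one CPU: exact-conversion and flood-fill oracles on 8³–32³
random volumes (50 and 20 replicates), segmentation recovery on a 128³
phantom (Dice = 1 noiseless; Dice ≥ 0.95 with noise at 10 % of the smallest
inter-band HU gap), the internal/external media contrast on 100 noisy
phantom replicates, collagen-fraction recovery at planted fractions
0.1–0.9 on 256² sections (10 seeds each, absolute error ≤ 0.05), and the
correlation structure on 200 simulated six-sample cohorts, where the
volume-normalized Pearson r must be positive in ≥ 95 % of replicates and
exceed the raw-HU r in the median replicate. The headline correlation of
the motivating study is tied to its six physical samples and is not
reproducible from synthetic data; what the cohort property checks is the
qualitative structure — normalization reveals the HU–collagen association
that dilution masks.

## Known limitations

* Thresholds ship uncalibrated; any real acquisition needs its own
  calibration against histology or phantoms of known composition.
* The volume normalization is cohort-relative: adding or removing the
  smallest sample rescales every normalized HU. Raw values are always
  reported alongside.
* Pooling internal/external media observations as separate points
  (`mode = "region"`, the default) treats within-sample regions as
  independent, which overstates the effective n; `mode = "sample"`
  averages to one point per sample first. Both are provided because the
  appropriate choice depends on the design.
* The DICOM layer covers exactly the uncompressed single-frame subset the
  pipeline needs; enhanced multi-frame objects and compressed transfer
  syntaxes are out of scope.
* At 6 µm, individual collagen fibres are at the resolution limit; the
  package quantifies content, not orientation, by design.
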