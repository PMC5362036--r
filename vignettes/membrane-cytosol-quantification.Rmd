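---
title: "Quantifying membrane-versus-cytosol protein localization in rod-shaped bacteria"
author: "memloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-versus-cytosol protein localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memloc)
```

## The measurement problem

Fluorescent fusions of membrane-recruited regulators — the motivating
case is a c-di-GMP effector in *Caulobacter crescentus* that leaves the
membrane when second-messenger levels peak — produce micrographs in
which each rod-shaped cell shows either a rim-enhanced ("membrane")
or a filled ("cytosolic") signal. The package scores this per cell:
given a fluorescence image and one closed polygon per cell, it reports
a single ratio and a binary class.

The procedure is deliberately simple and fully deterministic:

1. **Rasterize** the outline: a pixel belongs to the cell iff its
   center lies inside the polygon or on its boundary (even-odd rule).
2. **Partition** the cell mask into a membrane ring — the first
   `ringWidthPx` intracellular pixels flanking the outline — and the
   remaining interior (the cytosolic compartment).
3. **Average** the image over each compartment, optionally after
   subtracting a constant background.
4. **Ratio and classify**: `ratio = mean(ring) / mean(interior)`;
   `ratio > threshold` is membrane-associated, `ratio <= threshold`
   cytosolic (the boundary value is cytosolic).

Assumptions worth stating: one outline corresponds to one cell; the
outline traces the cell boundary (not an eroded or dilated version of
it); cells are wide enough that the ring leaves a non-empty interior;
and out-of-focus or neighbouring-cell light is negligible within each
outline.

## The ring definition

"The first four intracellular pixels flanking the outline" is
formalized as *Chebyshev distance ≤ 4 to the nearest exterior pixel*,
computed as four successive erosions with the 3×3 (8-connected)
structuring element. The two definitions provably coincide, which gives
an exact brute-force oracle: the test suite checks the erosion
implementation against a literal distance-transform on hundreds of
random masks, plus the worked 12×12-square case (144 pixels = 128 ring
+ 16 interior). A Euclidean-disc erosion would differ at corners; the
Chebyshev choice makes "four pixels" literal along both axes and the
diagonals. Everything outside the image counts as exterior, so masks
touching the border erode from the border too — such cells are flagged
`border` and excluded from cohort fractions by default, because their
ring would be truncated.

Cells whose ring swallows the whole mask are flagged `too_thin` with an
undefined ratio; a non-positive interior mean after background
subtraction yields flag `undefined_ratio`. Flagged cells stay in the
output table (auditable in `n_excluded`) but never enter fractions, and
no ratio is ever reported as ±Inf.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `ringWidthPx` | 4 | px | membrane-compartment depth; must be < half the cell width |
| `threshold` | 0.7 | – | class boundary on the ratio; calibrated on control populations |
| `backgroundMode` / `backgroundValue` | `none` / 0 | counts | constant background subtraction before averaging |
| `pixelSizeUm` | 0.066 | µm/px | converts Feret lengths to micrometres |

The ratio is invariant under multiplicative rescaling of the
background-subtracted image (tested to 1e-9), so exposure changes do
not move cells across the threshold — but additive background does
compress ratios towards 1, which is why the background mode is
explicit. For real images with unknown background the default is
`none`; for simulated images the known constant is subtracted, and both
behaviours are covered by tests.

## The synthetic generator

Real micrographs for this assay are not redistributable, so validation
uses a forward model of the imaging physics, not a cartoon:

- **Geometry.** Cells are spherocylinders (cylinder of diameter
  `widthPx` plus hemispherical caps) with uniform random orientation
  and lengths from a configurable distribution, placed by rejection
  sampling so footprints are disjoint (with a 2 px separation margin,
  so the stand-in segmenter cannot merge neighbours) and stay 8 px
  clear of the canvas border.
- **Projection.** A 2D image is the integral through the 3D cell: a
  cytosolic label projects the chord depth 2·√(r²−d²) at perpendicular
  axis distance d (spherical-cap equivalent at the poles, which falls
  out of measuring d from the cap center), a membrane label the path
  length through a shell of thickness t,
  2·(√(r²−d²) − √(max(0,(r−t)²−d²))), edge-peaked at d = r−t. This
  projection is what makes a cytosolic marker dimmer in the boundary
  ring than in the interior — the fact the 0.7 threshold exploits; a
  flat-disk model would not reproduce the classification.
- **Mixtures.** `membraneFraction` f renders
  f·membrane + (1−f)·cytosolic with both components normalized to the
  same total per-cell signal, so f is literally the fraction of label
  in the membrane. Noiseless ratios are strictly increasing in f
  (tested over f ∈ {0, 0.25, 0.5, 0.75, 1}).
- **Optics and noise**, in order: Gaussian PSF blur → constant
  background → Poisson resampling → additive Gaussian read noise →
  clamp at zero, mimicking photon emission then detector read-out. All
  randomness derives from one seed via deterministic per-stage hashing
  (`stageSeed`), so a cohort is a pure function of its configuration.

Default physics: width 15 px, lengths uniform 30–60 px, shell 1.5 px,
PSF σ 2 px, amplitude 1000, background 100, read-noise sd 20, 0.066
µm/px, 250 cells per cohort on a 1024×1024 canvas. Width > 8 px
guarantees a non-empty interior after the 4 px ring. At these defaults
the noiseless ratios are ≈ 0.64 for a pure cytosolic cell and ≈ 1.14
for a pure membrane cell, so the two control classes sit comfortably on
either side of 0.7 — which is what the calibration targets verify with
noise on.

What the generator does **not** emulate: phase-contrast images (ground
truth outlines stand in for a dedicated segmentation tool),
deconvolution (applied to the original micrographs before
quantification; the simulator quantifies blurred images directly),
polar foci or other sub-cellular structure beyond the two-compartment
mixture, cell growth and division (time-lapse series re-render a fixed
population under a per-frame membrane-fraction schedule), and
camera-specific artifacts (fixed-pattern noise, saturation — though a
`saturationLevel` flag is available). Passing tests therefore
demonstrate correctness of the quantification given correct outlines
and this image-formation model; they do not certify segmentation
quality on real phase-contrast data.

## Cohort statistics and calibration

`summarizePopulation` reports membrane/cytosolic counts and the
membrane-associated fraction with flagged cells excluded from the
denominator (both counts are reported, so the other convention is
recoverable — how unmeasurable cells entered published n-counts is
generally unstated). `calibrateThreshold` evaluates control
misclassification at a given threshold and searches for the optimum
only over candidate cut points at the observed ratio values, ties
resolved to the smallest candidate: deterministic and data-dependent,
with no arbitrary grid. Midpoints between observations are deliberately
not used; any value in an inter-observation gap classifies identically,
so the smallest achiever is a canonical representative.

Time-lapse traces are classified frame by frame; a **dispersal
episode** is a maximal run of ≥ 2 consecutive cytosolic frames. The
two-frame debounce suppresses single-frame noise without hiding
episodes at the ~12-minute scale reported for membrane-released
effectors at typical 3-minute frame intervals. Missing cells in a frame
break runs and are flagged `gap` rather than interpolated.

## Numerical choices

- Coordinates are 0-based, x = column, y = row, pixel centers at
  integers; polygon vertices are continuous. One convention, stated
  once, inherited everywhere.
- Rasterization is boundary-inclusive with an 1e-9 on-edge tolerance,
  making it orientation-independent and exactly reproducing the
  12×12 worked rectangle.
- Cell length is the Feret diameter (maximum pairwise vertex distance)
  of the outline, which equals pole-to-pole length for straight rods;
  it underestimates a medial-axis length for bent cells.
- Intensity TIFFs are 32-bit float, scaled by 1/65535 (a 16-bit camera
  full scale) to satisfy the [0,1] storage convention; the reader
  rescales, and the round trip is exact at float32 precision.
- Erosion pads with background, so image boundaries behave as cell
  exterior (consistent with the border flag).

## Validation problem sizes

The test suite validates at the cohort sizes the method is meant for:
two 250-cell control cohorts for calibration (perfect classification at
0.7), a 250-cell all-cytosolic cohort (0% membrane fraction), and a
parameter-recovery sweep of 40 runs (10 seeds × planted membrane
probabilities {0, 0.3, 0.7, 1}, 250 cells each) with mean absolute
fraction error ≤ 0.02. Oracle-equivalence and partition identities run
on hundreds of random masks. Smaller cohorts (tens of cells, ~300–600
px canvases) are used where the property under test does not depend on
cohort size.

## Known limitations

- The stand-in segmenter (smooth → Otsu → label → trace) is validated
  only on synthetic fluorescence images (per-cell IoU ≥ 0.8 against
  ground truth); it is not a phase-contrast segmentation tool.
- The Feret length and the rasterized-outline compartments differ
  slightly from sub-pixel mesh-based implementations; only the
  ratio-versus-length *relationship*, not absolute published lengths,
  is reproducible without the original pixel calibration.
- The two-compartment model cannot represent polar foci; a cell with a
  bright pole would be scored by where the focus falls relative to the
  ring.
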