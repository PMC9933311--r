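---
title: "Methods: quantifying wall fluorescence and lumen morphology in wood sections"
author: "lignoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying wall fluorescence and lumen morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the measurement
model, the estimators and their numerical conventions, the synthetic
ground-truth generator, and the design choices made where the published
procedure leaves the details open.

## Measurement model

A wood transverse section under UV excitation shows bright autofluorescent
cell walls (lignin phenolics, emission read in a single 420–470 nm band)
around dark cell lumens. One section is imaged as an exposure series —
the same field at strictly increasing exposure times, 100–3000 ms in
100 ms steps at 0.8 µm/pixel in the reference protocol — because
fluorescence levels differ strongly between pretreatment conditions, and a
single exposure would be under- or over-exposed for part of them. The
8-bit sensor clips at 255, so intensity must be read at an exposure where
the wall signal is on-scale.

Two families of quantities are extracted per section:

- **Wall fluorescence**: mean grey value over the cell-wall pixels of each
  *unmodified* frame, reported at a reference exposure (2000 ms). Only the
  wall *mask* is derived from processed images; intensities are never.
- **Lumen morphology**: per-lumen area (µm²), perimeter (µm) and
  circularity $4\pi A/P^2 \in (0,1]$. Circularity is the discriminating
  deformation marker: near 0.79 for intact rectangular tracheid lumens,
  near 1 for circular vessel lumens, dropping as cells collapse.

## Pipeline

Every frame is first normalised with contrast-limited adaptive histogram
equalization (CLAHE) to remove the smooth illumination inhomogeneity of
wavy sections. Parameters (block size 127 px, 256 bins, clip slope 3.0)
follow the de-facto defaults of the plugin ecosystem; they are exposed in
`claheParams()`. The enhanced frames are averaged into one projection
(round-half-up integer mean). Both automatic thresholds operate on this
enhanced projection:

- wall mask: Huang (spruce) or Moments (beechwood), keeping pixels
  *above* the level ("dark background" polarity);
- lumen mask: Li (spruce) or Minimum (beechwood), keeping pixels *at or
  below* the level (the lowest intensities). The two polarities partition
  the image exactly; the comparison at the level is fixed as `<=` on the
  dark side.

Thresholding the lumens on the enhanced *projection* rather than on a
single enhanced frame is a deliberate choice: the projection averages
sensor noise over the full series (30 frames reduce the noise sd by
~5.5×), which keeps lumen boundaries clean even for severely pretreated,
dim sections. The single-frame variant remains available
(`speciesProfile(..., lumenSource = "frame")`) and is recorded in the run
manifest, since the alternative reading of the published flow is a frame
at the reference exposure.

Species presets are fixed: spruce — Huang wall, Li lumen, 20 px particle
bound; beechwood — Moments wall, Minimum lumen, 500 px bound. The bounds
exclude noise specks (spruce) and the small fibre lumens that surround
the vessels of interest (beechwood).

## Threshold algorithms

All four operate on a 256-bin histogram; candidates are restricted to the
occupied grey range; criterion ties break toward the lower level so
results are platform-independent; a single-level histogram returns that
level with a `degenerate` flag instead of erroring, so batch runs survive
blank fields of view. All four are invariant to uniform scaling of the
counts.

- **Huang** minimises the fuzzy-membership entropy: class prototypes are
  the class mean greys, membership of level $g$ is
  $1/(1+|g-\mu_c|/C)$ with $C$ the occupied range, and the total Shannon
  entropy of memberships is scanned over all candidate levels.
- **Li** is the minimum-cross-entropy threshold via the Li–Tam fixed-point
  iteration $t \leftarrow (\mu_0-\mu_1)/(\ln\mu_0-\ln\mu_1)$, started at
  the histogram mean and stopped when the rounded level stops changing
  (change < 0.5). Because the rounded continuous fixed point can sit one
  level away from the discrete optimum, the result is slid to the adjacent
  minimum of the cross-entropy objective; the returned level then equals
  an exhaustive minimisation of the criterion (the test suite checks this
  equality on 200 random mixture histograms). Class means of zero are
  floored at $10^{-10}$ so mass at grey level 0 stays defined. Note that
  this criterion is intensity-weighted and therefore *not* symmetric
  under grey inversion — the threshold of a histogram and of its mirror
  do not sum to 255, unlike variance-based thresholds.
- **Moments** (Tsai) preserves the first three grey moments: the
  moment-preserving background fraction $p_0$ has a closed form, and the
  threshold is the smallest level at which the cumulative histogram
  fraction reaches $p_0$.
- **Minimum** smooths the histogram with a 3-bin mean filter until exactly
  two strict local maxima remain, then returns the minimum between them.
  Edge bins average the two available bins — a documented,
  reflection-free boundary rule that conserves mass wherever the edge
  bins are empty. A histogram that never becomes bimodal raises an error
  naming the iteration cap (default 10000); transient plateaus (fewer
  than two strict maxima) simply continue smoothing.

## Segmentation and morphometry

Lumen particles are 8-connected (background 4-connected), labelled in
raster-scan order of their first pixel. Interior holes are filled before
measurement by default — the measured object is the lumen, and noise
specks inside it must not punch holes — and border-touching particles are
excluded by default because truncation biases their area and circularity;
both are flags recorded in the manifest, since the published procedure
does not state its settings for them.

Area is the pixel count times the calibration squared. The perimeter
estimator is the package's main numerical design decision. Naive
boundary-step counting overestimates smooth contours by up to ~27 % and
single corner-cutting of the crack boundary still overestimates a
digitized disk by ~5.5 %, which would push measured circularities of
round vessels to ~0.9. Chain-code weight schemes (0.948/1.340 with corner
down-weighting) fix the disk but underestimate an axis-aligned square by
~8 %. Neither meets a ≤ 2 % contract on both shape families, so the
package instead measures the length of the 0.5-level subpixel contour of
the cross-kernel-smoothed (4-neighbour mean) region indicator, computed
with linear interpolation, and adds a fixed 0.58489 px per genuine
right-angle corner. Corners are detected on the crack boundary as two
perpendicular axis-aligned runs of at least 3 px meeting in a
marching-squares diagonal; digitized smooth contours never produce that
signature, so curved lumens receive no correction. The constant is the
exact per-corner deficit of the smoothed contour on axis-aligned squares
(scale-independent). Resulting errors: 20×20 square exact to 0.0 %,
100×25 rectangle exact, digitized disk r = 50 within +0.7 %, random
rotated ellipses within ~0.5 % — verified in the test suite, along with
an 8× supersampled-oracle agreement within 3 %. Circularity is clamped at
1 for tiny particles whose estimator satisfies $P^2 < 4\pi A$, matching
the convention of particle-analysis tools.

## Fluorometry

One wall mask per stack (from the projection), applied to every
unmodified frame. The curve reports the exact mean (conservation is
tested on integer frames), the mask pixel count, the wall area fraction,
and a saturation flag set when ≥ 1 % of wall pixels sit at 255, so
downstream statistics can exclude clipped exposures. `intensityAt()`
performs no interpolation: an absent exposure is an error listing the
available ones. Mean grey is written to CSV at two decimals, the
precision at which such intensities are conventionally reported.

At deep underexposure the measured mean exceeds the ideal wall intensity
because additive sensor noise is clipped at 0 but not compensated at the
top: with noise sd 5 the bias is visible wherever the true signal is
comparable to the noise (here, below roughly 500 ms for an untreated
wall). The invariant suite therefore checks the 5 % accuracy contract at
exposures whose true wall grey is at least twice the noise sd; the
reporting exposure of 2000 ms sits far above that floor in all study
conditions.

## Synthetic sections and calibration

The generator renders what the pipeline must invert, with ground truth
defined on the pre-noise, pre-illumination geometry:

- **Geometry.** Each lumen is star-shaped about its centre,
  $r(\varphi) = r_0(\varphi)\,(1+\sum_{k=2}^{6} a_k\cos(k\varphi+\psi_k))$,
  with $r_0$ a rounded rectangle (spruce tracheids, laid on a jittered
  heterogeneous grid with 5 px walls) or an ellipse (beechwood vessels,
  dart-thrown largest-first among sub-500 px fibre lumens so the species
  size filter is exercised). Sizes are lognormal — positive and
  right-skewed, matching the broad spread of published per-condition
  standard deviations (relative SDs near 0.6), which is also what makes
  the pooled mean perimeter consistent with the pooled mean area and
  circularity of a condition.
- **Severity** in [0, 1] simultaneously shrinks radii (up to −30 %
  linear), raises the harmonic boundary amplitudes and aspect spread
  (down to mean circularities ≈ 0.66 for spruce, ≈ 0.47 for beechwood at
  severity 1 — chosen so the dial spans the full range observed across
  pretreatment conditions), and scales the wall gain by
  $(1-0.55\,\mathrm{severity})$, mirroring the joint morphological and
  chemical effect of harsher pretreatment. Monotonicity of true mean
  circularity and area in severity is asserted by construction, not as a
  biological claim.
- **Rendering.** Wall intensity $\min(255, g\,e)$ at exposure $e$, lumens
  near dark (4 % of the wall gain), a 0.7 px linear edge ramp standing in
  for optical blur, a smooth multiplicative illumination field (mean 1,
  default ±20 %, period a large fraction of the image so CLAHE can
  compensate it), additive Gaussian noise (sd 5 grey levels, a plausible
  8-bit camera noise floor), round-half-up and 8-bit clipping. All
  randomness derives from the spec seed; a spec regenerates its section
  bit-identically, and the YAML-serialized spec is the exact re-generation
  manifest.
- **Ground truth.** Perimeter from the 512-gon arc length of each exact
  boundary, area from an 8× supersampled rasterization (8× and 16× agree
  within 0.5 %), circularity from the two, and the true wall grey per
  exposure as the mean of the ideal noise-free, unit-illumination frame
  over the true wall mask — so boundary mixture pixels affect truth and
  measurement alike.

`calibrateToTarget()` finds a spec whose ground-truth means equal a
target (area, circularity, wall grey at 2000 ms): a bisection on a single
deformation dial (regularized shapes at one end, full severity at the
other; mean circularity is monotone along it), an exact quadratic size
rescaling for the area, and a closed-form wall gain from the mean lumen
coverage of wall pixels. Circularity targets outside the geometrically
achievable range of the species raise an error; a target within 0.02 of
the range edge (e.g. a perfect circle) is clamped to it. The search uses
fast polygon (shoelace) geometry; the emitted truth still uses the
supersampled oracle.

What the generator does *not* emulate: real optics (point-spread
function, 12 µm depth of field), photobleaching, spectral structure,
rays/parenchyma, growth-ring periodicity, cell-wall thickness variation,
or touching lumens that would require watershed splitting. Passing
recovery tests therefore demonstrates that the pipeline correctly inverts
this model class at realistic noise, contrast and morphology — not that
it handles every artefact of real macrographs.

## Statistics

Condition summaries pool particles across a condition's sections
(mean ± SD of perimeter, area, circularity) and average wall grey at the
reference exposure per section, then across sections — the SD across
sections is `NA` for a single section. `pearsonR()` validates and
delegates to `stats::cor`. `holmSidakAdjust()` implements the step-down
Šidák adjustment ($1-(1-p_{(i)})^{k-i+1}$, monotonised, capped at 1,
returned in input order); no further test machinery is provided.

## Conventions and I/O

Round-half-up is the single integerisation rule (conversion, projection,
rendering). RGB input is converted by the unweighted channel mean by
default — the appropriate channel weighting of an autofluorescence image
is not determined, so Rec.601 luminance weights are an option. Stacks are
stored as uncompressed multi-page 8-bit TIFF with a plain-text YAML
sidecar carrying the exposure series and pixel size (the installed TIFF
writer cannot set description/resolution tags); the round-trip is
bit-exact. Exposure times are explicit metadata; a filename-pattern
helper exists as convenience only.

## Problem sizes

The recovery fixtures run the full pipeline on 1200 tracheids
(≈ 1500×1600 px, 30 exposures) and 250 vessels (≈ 2200×2200 px) — large
enough that pooled means are stable to well within the acceptance
tolerances (±0.05 circularity, ±5 % area/perimeter/intensity), and small
enough that each fixture completes in roughly a minute on one CPU. Unit and
property tests use sections of 10–70 lumens.

## Known limitations

- Merged lumens (wall breaches) are measured as one particle; no
  watershed splitting.
- Wall thickness is not measured.
- The perimeter estimator's corner correction targets right angles;
  obtuse polygon corners in digitized shapes are smoothed and slightly
  shortened (sub-percent for the shapes measured here).
- Sub-noise-floor exposures carry a positive clipping bias in measured
  intensity (flagged analysis above); report at exposures on-scale.
- The CLAHE backend requantises to 8 bits; masks derived from images
  whose brightness is rescaled by an exact factor can differ in a
  sub-percent fraction of boundary pixels.
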