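# lignoquant

Automated quantification of cell-wall fluorescence and cell-lumen
morphology from multi-exposure fluorescence macrographs of wood
transverse sections.

## The problem

Steam explosion and similar pretreatments alter lignocellulosic biomass in
two coupled ways that are visible in transverse sections under UV-excited
fluorescence macroscopy: the lignin autofluorescence of the cell walls
fades, and the cells themselves shrink and deform — spruce tracheids lose
their rectangular outline, beechwood vessels their circular one. Measuring
both effects on thousands of cells per section requires an automated image
pipeline. `lignoquant` implements such a pipeline as a tested R library
plus a small command-line tool, together with a synthetic section
generator that provides per-lumen ground truth, so every stage of the
procedure can be verified quantitatively without access to specimen
images.

## The procedure

Input is a stack of 8-bit grey frames of one section acquired at a series
of exposure times (100–3000 ms in 100 ms steps at 0.8 µm/pixel in the
reference protocol). The analysis runs two branches over it:

1. **Enhance & project.** Each frame is contrast-normalised with CLAHE
   (block 127 px, 256 bins, slope 3) to compensate the illumination
   inhomogeneity of wavy sections; the enhanced stack is averaged into a
   single projection.
2. **Wall branch.** An automatic histogram threshold with dark-background
   polarity — Huang's fuzzy-entropy threshold for spruce, Tsai's
   moment-preserving threshold for beechwood — selects the bright cell
   walls on the projection. The mean grey value of the *unmodified*
   frames over this wall mask, per exposure, is the fluorescence curve;
   wall intensity is reported at 2000 ms.
3. **Lumen branch.** A second threshold — Li's minimum-cross-entropy for
   spruce, the iterated-smoothing "Minimum" for beechwood — selects the
   dark lumens on the enhanced projection. Connected particles
   (8-connected, holes filled) are filtered by the species size bound
   (20 px for spruce tracheids, 500 px for beechwood vessels, border
   particles excluded) and measured:

   - area `A` (pixel count × calibration²),
   - perimeter `P` (subpixel boundary estimator, ≤ 2 % error for convex
     shapes ≥ 20 px diameter),
   - circularity `4πA/P²` ∈ (0, 1], clamped at 1 — the shape descriptor
     that discriminates intact from collapsed cells.

The synthetic generator (`sectionSpec()` / `generateSection()`) renders
exposure stacks of either species with a severity dial in [0, 1] driving
lumen shrinkage, boundary deformation and wall-fluorescence loss, plus
illumination inhomogeneity, sensor noise and 8-bit clipping; it emits
exact per-lumen geometry and the true wall intensity per exposure.
`calibrateToTarget()` tunes a spec so its ground-truth means equal a
requested area / circularity / wall-grey triple.

## Worked example

```r
library(lignoquant)

# a synthetic untreated beechwood section: 40 vessels among fibre lumens
spec <- sectionSpec("beechwood", nCells = 40, seed = 17)
sect <- generateSection(spec)

res <- runSection(sect$stack, speciesProfile("beechwood"))
nrow(res$particles)                     # 40 vessel lumens found
round(mean(res$particles$circularity), 3)
round(intensityAt(res$curve, 2000), 2)  # mean wall grey at 2000 ms
round(mean(groundTruth(sect$truth)$true_circularity[
  groundTruth(sect$truth)$type == "vessel"]), 3)
```

prints

```
[1] 39
[1] 0.975
[1] 23.64
[1] 0.991
```

i.e. the pipeline finds 39 of the 40 vessels (one sits below the 500 px
bound after deformation), measures their pooled mean circularity 0.975
against a generator truth of 0.991, and reads a wall intensity of 23.64
grey levels at 2000 ms against a true wall-curve value of 23.27 —
recovery within the tolerances the test suite enforces (±0.05
circularity, ±5 % intensity).

The same flow from a shell:

```sh
Rscript inst/scripts/lignoquant simulate --config spec.yaml \
    --out-stack section.tif --out-truth truth.csv
Rscript inst/scripts/lignoquant run --stack section.tif \
    --species beechwood --outdir out/
Rscript inst/scripts/lignoquant summarize --particles out/particles.csv \
    --curves out/fluorescence.csv --label untreated --out summary.csv
```

## Package layout

- `R/` — S4 classes (`GreyImage`, `ExposureStack`, `SpeciesProfile`,
  `SectionSpec`, …), threshold algorithms, segmentation, fluorometry,
  generator, pipeline, CLI.
- `tests/testthat/` — unit, property and acceptance tests with
  independent brute-force oracles.
- `vignettes/lignoquant-methods.Rmd` — the methods vignette: model,
  estimators, generator design, numerical conventions, limitations.
- `inst/scripts/lignoquant` — the command-line entry point.
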