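#' @import methods
NULL

#' GreyImage: a calibrated 8-bit grey-level image
#'
#' A single 2-D intensity field with integer grey levels in \[0, 255\] and a
#' physical pixel-size calibration in micrometres per pixel edge. This is the
#' elementary frame type of the package; fluorescence macrographs are held as
#' ordered collections of these (see [ExposureStack-class]).
#'
#' @slot pixels integer matrix, rows indexing y and columns indexing x, with
#'   values in \[0, 255\].
#' @slot pixelSizeUm positive scalar, micrometres per pixel edge.
#' @seealso [GreyImage()], [ExposureStack-class]
#' @exportClass GreyImage
setClass("GreyImage",
  representation(pixels = "matrix", pixelSizeUm = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) < 1L || ncol(p) < 1L) return("both image dimensions must be >= 1")
    if (anyNA(p)) return("pixels must not contain NA")
    if (any(p < 0 | p > 255)) return("grey levels must lie in [0, 255]")
    if (any(p != floor(p))) return("grey levels must be integers")
    ps <- object@pixelSizeUm
    if (length(ps) != 1L || !is.finite(ps) || ps <= 0)
      return("pixelSizeUm must be a finite positive scalar")
    TRUE
  })

#' ExposureStack: one section imaged at a series of exposure times
#'
#' An ordered list of [GreyImage-class] frames of identical dimensions and
#' calibration, together with their strictly increasing exposure times in
#' milliseconds. Fluorescence macrographs of wood sections are acquired from
#' under- to over-exposure (100--3000 ms in 100 ms steps in the reference
#' acquisition protocol) so that wall intensity can be read below sensor
#' saturation at some exposure for every sample.
#'
#' @slot frames list of [GreyImage-class] objects.
#' @slot exposureMs numeric vector of exposure times (ms), strictly
#'   increasing, one per frame.
#' @seealso [readStack()], [writeStack()], [averageProjection()]
#' @exportClass ExposureStack
setClass("ExposureStack",
  representation(frames = "list", exposureMs = "numeric"),
  validity = function(object) {
    fr <- object@frames
    if (length(fr) < 1L) return("a stack needs at least one frame")
    if (!all(vapply(fr, is, TRUE, "GreyImage")))
      return("all frames must be GreyImage objects")
    ex <- object@exposureMs
    if (length(ex) != length(fr))
      return("exposureMs must have one entry per frame")
    if (anyNA(ex) || any(!is.finite(ex)) || any(ex <= 0))
      return("exposure times must be finite and positive")
    if (any(diff(ex) <= 0)) return("exposure times must be strictly increasing")
    d <- dim(fr[[1L]]@pixels)
    if (!all(vapply(fr, function(f) identical(dim(f@pixels), d), TRUE)))
      return("all frames must share the same dimensions")
    ps <- fr[[1L]]@pixelSizeUm
    if (!all(vapply(fr, function(f) isTRUE(all.equal(f@pixelSizeUm, ps)), TRUE)))
      return("all frames must share the same pixel size")
    TRUE
  })

#' IntensityHistogram: 256-bin grey-level histogram
#'
#' Pixel counts per grey level 0--255, the common input of the four automatic
#' threshold algorithms ([thresholdHuang()], [thresholdLi()],
#' [thresholdMoments()], [thresholdMinimum()]).
#'
#' @slot counts non-negative integer vector of length 256, `counts[g + 1]`
#'   holding the number of pixels at grey level `g`.
#' @slot total sum of `counts`.
#' @seealso [computeHistogram()]
#' @exportClass IntensityHistogram
setClass("IntensityHistogram",
  representation(counts = "numeric", total = "numeric"),
  validity = function(object) {
    ct <- object@counts
    if (length(ct) != 256L) return("counts must have length 256")
    if (anyNA(ct) || any(ct < 0)) return("counts must be non-negative")
    if (!isTRUE(all.equal(object@total, sum(ct))))
      return("total must equal sum(counts)")
    if (object@total <= 0) return("histogram must contain at least one pixel")
    TRUE
  })

#' ThresholdResult: the outcome of an automatic threshold
#'
#' @slot level integer grey level in \[0, 255\].
#' @slot method one of `"huang"`, `"li"`, `"moments"`, `"minimum"`.
#' @slot darkBackground logical; `TRUE` encodes the "dark" polarity of the
#'   named ImageJ-style methods (bright foreground above the level).
#' @slot degenerate logical; `TRUE` when the histogram had a single occupied
#'   level, in which case `level` is that level and downstream code should
#'   treat the field of view as blank.
#' @seealso [autoThreshold()], [applyThreshold()]
#' @exportClass ThresholdResult
setClass("ThresholdResult",
  representation(level = "integer", method = "character",
                 darkBackground = "logical", degenerate = "logical"),
  prototype(darkBackground = TRUE, degenerate = FALSE),
  validity = function(object) {
    if (object@level < 0L || object@level > 255L)
      return("level must lie in [0, 255]")
    if (!object@method %in% c("huang", "li", "moments", "minimum"))
      return("method must be one of huang, li, moments, minimum")
    TRUE
  })

#' ClaheParams: parameters of contrast-limited adaptive histogram equalization
#'
#' Defaults mirror the de-facto defaults of the CLAHE plugin ecosystem
#' (block size 127 px, 256 histogram bins, maximum slope 3).
#'
#' @slot blockSize pixels per contextual tile edge (odd, >= 3).
#' @slot histogramBins number of histogram bins, in \[2, 256\].
#' @slot maxSlope clip limit (> 1); larger values allow stronger local
#'   contrast amplification.
#' @seealso [claheEnhance()]
#' @exportClass ClaheParams
setClass("ClaheParams",
  representation(blockSize = "integer", histogramBins = "integer",
                 maxSlope = "numeric"),
  prototype(blockSize = 127L, histogramBins = 256L, maxSlope = 3),
  validity = function(object) {
    if (object@blockSize < 3L || object@blockSize %% 2L == 0L)
      return("blockSize must be odd and >= 3")
    if (object@histogramBins < 2L || object@histogramBins > 256L)
      return("histogramBins must lie in [2, 256]")
    if (!is.finite(object@maxSlope) || object@maxSlope <= 1)
      return("maxSlope must be finite and > 1")
    TRUE
  })

#' ParticleFilter: size and edge filtering of segmented lumens
#'
#' @slot minAreaPx lower particle-size bound in pixels (>= 1); 20 px for the
#'   spruce procedure, 500 px for beechwood.
#' @slot excludeEdgeParticles drop lumens touching the image border, whose
#'   area and circularity are biased by truncation (default `TRUE`).
#' @seealso [filterParticles()], [measureLumens()]
#' @exportClass ParticleFilter
setClass("ParticleFilter",
  representation(minAreaPx = "integer", excludeEdgeParticles = "logical"),
  prototype(minAreaPx = 1L, excludeEdgeParticles = TRUE),
  validity = function(object) {
    if (object@minAreaPx < 1L) return("minAreaPx must be >= 1")
    TRUE
  })

#' SpeciesProfile: the per-species analysis preset
#'
#' Bundles the threshold methods and particle-size bound of the automated
#' procedure. The fixed presets are: spruce — wall threshold Huang (dark),
#' lumen threshold Li (dark), minimum particle size 20 px; beechwood — wall
#' threshold Moments (dark), lumen threshold Minimum, minimum size 500 px.
#'
#' @slot name `"spruce"`, `"beechwood"` or `"custom"`.
#' @slot wallThreshold threshold method for the cell-wall mask.
#' @slot lumenThreshold threshold method for the lumen mask.
#' @slot minAreaPx particle-size lower bound (px).
#' @slot clahe [ClaheParams-class] used for contrast enhancement.
#' @slot excludeEdgeParticles,fillHoles segmentation flags (see
#'   [measureLumens()]).
#' @slot lumenSource image the lumen threshold operates on:
#'   `"projection"` (default; the contrast-enhanced average image, as in the
#'   published flow) or `"frame"` (the enhanced frame at the reference
#'   exposure).
#' @slot referenceExposureMs exposure (ms) at which wall fluorescence is
#'   reported and, with `lumenSource = "frame"`, at which the lumen branch
#'   segments (default 2000).
#' @seealso [speciesProfile()], [runSection()]
#' @exportClass SpeciesProfile
setClass("SpeciesProfile",
  representation(name = "character", wallThreshold = "character",
                 lumenThreshold = "character", minAreaPx = "integer",
                 clahe = "ClaheParams", excludeEdgeParticles = "logical",
                 fillHoles = "logical", lumenSource = "character",
                 referenceExposureMs = "numeric"),
  prototype(lumenSource = "projection"),
  validity = function(object) {
    ok <- c("huang", "li", "moments", "minimum")
    if (!object@wallThreshold %in% ok) return("unknown wall threshold method")
    if (!object@lumenThreshold %in% ok) return("unknown lumen threshold method")
    if (!object@lumenSource %in% c("projection", "frame"))
      return("lumenSource must be 'projection' or 'frame'")
    if (object@minAreaPx < 1L) return("minAreaPx must be >= 1")
    if (object@referenceExposureMs <= 0) return("referenceExposureMs must be > 0")
    TRUE
  })

#' SectionSpec: parameters of the synthetic wood-section generator
#'
#' Describes one simulated transverse section: the species geometry (a
#' quasi-periodic tracheid honeycomb for spruce, scattered large vessels
#' among small fibre lumens for beechwood), the deformation severity, the
#' wall fluorescence response, illumination inhomogeneity and sensor noise.
#' All randomness derives from `seed`; a spec regenerates its section
#' bit-identically.
#'
#' @slot speciesMode `"spruce"` or `"beechwood"`.
#' @slot nCells target lumen count (tracheids, or vessels for beechwood;
#'   beechwood sections additionally receive sub-threshold fibre lumens).
#' @slot imageSizePx integer `(width, height)` in px, or `NA` to size the
#'   image automatically from `nCells` and the lumen size distribution.
#' @slot pixelSizeUm micrometres per pixel (0.8 in the reference protocol).
#' @slot exposuresMs exposure series (ms), strictly increasing.
#' @slot severity deformation parameter in \[0, 1\]: 0 reproduces intact
#'   (untreated) geometry; 1 applies the full radial shrinkage, boundary
#'   deformation and wall-fluorescence loss of a severely pretreated sample.
#' @slot sizeScale multiplier on all lumen linear dimensions (calibration
#'   handle; 1 = species defaults).
#' @slot wallGain fluorescence gain g: ideal wall grey at exposure e ms is
#'   `min(255, g * (1 - 0.55 * severity) * e)`.
#' @slot lumenGainFrac lumen background gain as a fraction of the effective
#'   wall gain (lumens are nearly dark).
#' @slot noiseSd additive Gaussian sensor noise (grey levels) before 8-bit
#'   clipping.
#' @slot illuminationAmplitude relative amplitude of the smooth multiplicative
#'   illumination field emulating wavy sections (0.2 = +/-20 percent).
#' @slot edgeSoftnessPx width (px) of the linear wall/lumen transition ramp
#'   emulating optical blur.
#' @slot shape named list of species shape parameters (size distributions,
#'   aspect spread, corner radius, harmonic deformation scales, wall
#'   thickness, regularity); see [sectionSpec()] for defaults.
#' @slot seed integer RNG seed.
#' @seealso [sectionSpec()], [generateSection()], [calibrateToTarget()]
#' @exportClass SectionSpec
setClass("SectionSpec",
  representation(speciesMode = "character", nCells = "integer",
                 imageSizePx = "integer", pixelSizeUm = "numeric",
                 exposuresMs = "numeric", severity = "numeric",
                 sizeScale = "numeric", wallGain = "numeric",
                 lumenGainFrac = "numeric", noiseSd = "numeric",
                 illuminationAmplitude = "numeric", edgeSoftnessPx = "numeric",
                 shape = "list", seed = "integer"),
  validity = function(object) {
    if (!object@speciesMode %in% c("spruce", "beechwood"))
      return("speciesMode must be 'spruce' or 'beechwood'")
    if (object@nCells < 1L) return("nCells must be >= 1")
    if (object@severity < 0 || object@severity > 1)
      return("severity must lie in [0, 1]")
    if (object@wallGain <= 0) return("wallGain must be > 0")
    if (object@sizeScale <= 0) return("sizeScale must be > 0")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@illuminationAmplitude < 0 || object@illuminationAmplitude >= 1)
      return("illuminationAmplitude must lie in [0, 1)")
    if (any(diff(object@exposuresMs) <= 0) || any(object@exposuresMs <= 0))
      return("exposuresMs must be positive and strictly increasing")
    TRUE
  })

#' SectionTruth: per-lumen ground truth of a synthetic section
#'
#' Emitted by [generateSection()] alongside the rendered stack. Ground truth
#' is defined on the pre-noise, pre-illumination geometry so that pipeline
#' measurement error is attributable and bounded: lumen area comes from an
#' 8x supersampled rasterization of the boundary polygons, perimeter from
#' polygon arc length, and the true wall grey per exposure is the mean of the
#' ideal (noise-free, unit-illumination) frame over the true wall mask.
#'
#' @slot lumens data.frame with one row per lumen: `id`, `type` (tracheid,
#'   vessel or fibre), `cx`, `cy` (px), `true_area_um2`,
#'   `true_perimeter_um`, `true_circularity`, `area_px_1x`.
#' @slot polygons list of 2-column matrices (x, y in px), one boundary
#'   polygon per lumen.
#' @slot wallMask logical matrix, `TRUE` on true wall pixels at 1x.
#' @slot wallCurve data.frame `exposure_ms`, `true_mean_grey`.
#' @slot spec the generating [SectionSpec-class].
#' @exportClass SectionTruth
setClass("SectionTruth",
  representation(lumens = "data.frame", polygons = "list",
                 wallMask = "matrix", wallCurve = "data.frame",
                 spec = "SectionSpec"))

setMethod("show", "GreyImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GreyImage %d x %d px (%.3g um/px), grey range [%d, %d]\n",
              d[2L], d[1L], object@pixelSizeUm,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ExposureStack", function(object) {
  d <- dim(object@frames[[1L]]@pixels)
  ex <- object@exposureMs
  cat(sprintf("ExposureStack: %d frames, %d x %d px (%.3g um/px), exposures %g..%g ms\n",
              length(ex), d[2L], d[1L], object@frames[[1L]]@pixelSizeUm,
              min(ex), max(ex)))
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult: %s%s, level %d%s\n", object@method,
              if (object@darkBackground) " (dark)" else "", object@level,
              if (object@degenerate) " [degenerate histogram]" else ""))
})

setMethod("show", "SpeciesProfile", function(object) {
  cat(sprintf(
    "SpeciesProfile '%s': wall=%s(dark), lumen=%s, min %d px, ref %g ms\n",
    object@name, object@wallThreshold, object@lumenThreshold,
    object@minAreaPx, object@referenceExposureMs))
})

setMethod("show", "SectionSpec", function(object) {
  sz <- if (anyNA(object@imageSizePx)) "auto" else
    paste(object@imageSizePx, collapse = " x ")
  cat(sprintf(
    "SectionSpec %s: %d cells, image %s px, severity %.2f, scale %.3f, seed %d\n",
    object@speciesMode, object@nCells, sz, object@severity,
    object@sizeScale, object@seed))
})

setMethod("show", "SectionTruth", function(object) {
  cat(sprintf(
    "SectionTruth: %d lumens (%s), mean area %.1f um2, mean circularity %.3f\n",
    nrow(object@lumens), object@spec@speciesMode,
    mean(object@lumens$true_area_um2), mean(object@lumens$true_circularity)))
})
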