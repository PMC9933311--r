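#' Species analysis presets
#'
#' Returns the fixed per-species profile of the automated procedure:
#' spruce — wall threshold Huang (dark), lumen threshold Li (dark),
#' minimum particle size 20 px; beechwood — wall threshold Moments (dark),
#' lumen threshold Minimum, minimum size 500 px. `"custom"` starts from the
#' spruce preset with every field overridable.
#'
#' @param name `"spruce"`, `"beechwood"` or `"custom"`.
#' @param wallThreshold,lumenThreshold,minAreaPx,clahe,excludeEdgeParticles,fillHoles,lumenSource,referenceExposureMs
#'   overrides of the preset fields (see [SpeciesProfile-class]).
#' @return a [SpeciesProfile-class].
#' @export
speciesProfile <- function(name = c("spruce", "beechwood", "custom"),
                           wallThreshold = NULL, lumenThreshold = NULL,
                           minAreaPx = NULL, clahe = claheParams(),
                           excludeEdgeParticles = TRUE, fillHoles = TRUE,
                           lumenSource = c("projection", "frame"),
                           referenceExposureMs = 2000) {
  lumenSource <- match.arg(lumenSource)
  name <- match.arg(name)
  preset <- switch(name,
    spruce = list(wall = "huang", lumen = "li", minArea = 20L),
    beechwood = list(wall = "moments", lumen = "minimum", minArea = 500L),
    custom = list(wall = "huang", lumen = "li", minArea = 20L))
  new("SpeciesProfile", name = name,
      wallThreshold = if (is.null(wallThreshold)) preset$wall else wallThreshold,
      lumenThreshold = if (is.null(lumenThreshold)) preset$lumen else lumenThreshold,
      minAreaPx = as.integer(if (is.null(minAreaPx)) preset$minArea else minAreaPx),
      clahe = clahe, excludeEdgeParticles = excludeEdgeParticles,
      fillHoles = fillHoles, lumenSource = lumenSource,
      referenceExposureMs = referenceExposureMs)
}

#' Run the full analysis procedure on one section
#'
#' Executes both branches of the automated workflow on a multi-exposure
#' stack. Every frame is contrast-enhanced (CLAHE) and the enhanced stack is
#' averaged once into the enhanced projection. Wall branch: the profile's
#' wall threshold on the projection (dark polarity), then mean wall
#' intensity per exposure measured on the unmodified stack through the
#' resulting mask. Lumen branch: the profile's lumen threshold applied
#' at-or-below (lowest intensities) on the enhanced projection (default) or
#' on the enhanced frame at the reference exposure
#' (`lumenSource = "frame"`; the nearest frame is used and recorded in the
#' manifest), then particle labeling, species size/edge filtering and
#' morphometry. A section failing one branch still reports the other, with
#' status flags.
#'
#' @param stack an [ExposureStack-class].
#' @param profile a [SpeciesProfile-class].
#' @return list with `particles` (data.frame, see [measureLumens()]),
#'   `curve` (data.frame, see [measureWallIntensity()], or `NULL`),
#'   `wallMask` and `lumenMask` (logical matrices or `NULL`) and `manifest`
#'   (named list logging every parameter, threshold level and status flag;
#'   re-running from it reproduces the outputs bit-exactly).
#' @export
runSection <- function(stack, profile = speciesProfile("spruce")) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("lignoquant")),
    profile = list(name = profile@name,
                   wall_threshold = profile@wallThreshold,
                   lumen_threshold = profile@lumenThreshold,
                   min_area_px = profile@minAreaPx,
                   exclude_edge_particles = profile@excludeEdgeParticles,
                   fill_holes = profile@fillHoles,
                   lumen_source = profile@lumenSource,
                   reference_exposure_ms = profile@referenceExposureMs,
                   clahe = list(block_size = profile@clahe@blockSize,
                                histogram_bins = profile@clahe@histogramBins,
                                max_slope = profile@clahe@maxSlope)),
    stack = list(n_frames = nFrames(stack),
                 exposures_ms = exposureTimes(stack),
                 pixel_size_um = pixelSize(stack)),
    status = list(wall_branch = "ok", lumen_branch = "ok"))

  enhProj <- averageProjection(claheStack(stack, profile@clahe))

  wm <- NULL; curve <- NULL
  wallOut <- tryCatch({
    th <- autoThreshold(computeHistogram(enhProj), profile@wallThreshold)
    wm <- applyThreshold(enhProj, th, "above")
    attr(wm, "threshold") <- th
    manifest$wall_threshold_level <- th@level
    manifest$wall_threshold_degenerate <- th@degenerate
    curve <- measureWallIntensity(stack, wm)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(wallOut)) manifest$status$wall_branch <- wallOut

  lumenMask <- NULL
  particles <- NULL
  lumenOut <- tryCatch({
    enh <- if (profile@lumenSource == "frame") {
      i <- which.min(abs(exposureTimes(stack) - profile@referenceExposureMs))
      manifest$lumen_reference_frame_ms <- exposureTimes(stack)[i]
      claheEnhance(frames(stack)[[i]], profile@clahe)
    } else enhProj
    th <- autoThreshold(computeHistogram(enh), profile@lumenThreshold)
    manifest$lumen_threshold_level <- th@level
    manifest$lumen_threshold_degenerate <- th@degenerate
    lumenMask <- applyThreshold(enh, th, "at_or_below")
    particles <- measureLumens(
      lumenMask,
      particleFilter(profile@minAreaPx, profile@excludeEdgeParticles),
      pixelSize(stack), fillHoles = profile@fillHoles)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(lumenOut)) manifest$status$lumen_branch <- lumenOut

  list(particles = particles, curve = curve, wallMask = wm,
       lumenMask = lumenMask, manifest = manifest)
}

#' Summarise one condition over its analysed sections
#'
#' Pooling convention of condition summaries: morphology statistics (mean
#' and SD of perimeter, area, circularity) pool all particles across the
#' condition's sections; wall fluorescence at the reference exposure is
#' taken per section and then averaged across sections, with the SD across
#' sections (`NA` when a single section was analysed).
#'
#' @param particlesList list of particle data.frames, one per section.
#' @param curvesList list of fluorescence curves, one per section.
#' @param referenceExposureMs exposure (ms) at which fluorescence is
#'   reported (default 2000).
#' @param label condition label.
#' @return one-row data.frame: `condition`, `n_sections`, `n_particles`,
#'   `perimeter_um_mean`/`_sd`, `area_um2_mean`/`_sd`,
#'   `circularity_mean`/`_sd`, `wall_grey_mean`/`_sd`.
#' @export
summarizeCondition <- function(particlesList, curvesList,
                               referenceExposureMs = 2000,
                               label = "condition") {
  assertThat(length(particlesList) >= 1L, "at least one section is required")
  pooled <- do.call(rbind, particlesList)
  greys <- vapply(curvesList, intensityAt, numeric(1L),
                  exposureMs = referenceExposureMs)
  sdOrNA <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  data.frame(
    condition = label,
    n_sections = length(particlesList),
    n_particles = if (is.null(pooled)) 0L else nrow(pooled),
    perimeter_um_mean = mean(pooled$perimeter_um),
    perimeter_um_sd = sdOrNA(pooled$perimeter_um),
    area_um2_mean = mean(pooled$area_um2),
    area_um2_sd = sdOrNA(pooled$area_um2),
    circularity_mean = mean(pooled$circularity),
    circularity_sd = sdOrNA(pooled$circularity),
    wall_grey_mean = mean(greys),
    wall_grey_sd = sdOrNA(greys))
}
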