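#' Build the cell-wall mask of a stack
#'
#' The wall branch of the procedure: every frame is contrast-enhanced
#' (CLAHE), the enhanced stack is averaged into a single projection, the
#' named automatic threshold is computed on the projection's histogram, and
#' pixels above the level (dark-background polarity) form the wall mask.
#' The mask is computed once per stack and then applied to every frame of
#' the unmodified stack by [measureWallIntensity()].
#'
#' @param stack an [ExposureStack-class].
#' @param method threshold method name (`"huang"` for the spruce preset,
#'   `"moments"` for beechwood).
#' @param clahe a [ClaheParams-class].
#' @return logical matrix of wall pixels, with the [ThresholdResult-class]
#'   attached as attribute `"threshold"` (carrying the degeneracy flag for
#'   blank fields of view).
#' @export
wallMask <- function(stack, method = "huang", clahe = claheParams()) {
  proj <- averageProjection(claheStack(stack, clahe))
  th <- autoThreshold(computeHistogram(proj), method)
  mask <- applyThreshold(proj, th, "above")
  attr(mask, "threshold") <- th
  mask
}

#' Measure mean wall fluorescence along the exposure series
#'
#' For each frame of the unmodified stack (intensities untouched by any
#' enhancement), the mean grey value over the wall-mask pixels is recorded,
#' giving the fluorescence-versus-exposure curve of the section. Frames in
#' which at least 1 percent of wall pixels sit at 255 are flagged as
#' saturated so downstream statistics can exclude them.
#'
#' @param stack an [ExposureStack-class].
#' @param mask logical wall mask of the frames' dimensions, non-empty.
#' @return data.frame (the fluorescence curve), ordered by exposure:
#'   `exposure_ms`, `mean_grey`, `n_pixels`, `wall_fraction`, `saturated`.
#' @export
measureWallIntensity <- function(stack, mask) {
  d <- dim(stack@frames[[1L]]@pixels)
  assertThat(is.logical(mask) && identical(dim(mask), d),
             "mask must be a logical matrix matching the frame dimensions")
  n <- sum(mask)
  assertThat(n > 0L, "wall mask is empty")
  vals <- vapply(stack@frames, function(f) {
    v <- f@pixels[mask]
    c(mean(v), sum(v == 255L))
  }, numeric(2L))
  data.frame(exposure_ms = stack@exposureMs,
             mean_grey = vals[1L, ],
             n_pixels = n,
             wall_fraction = n / prod(d),
             saturated = vals[2L, ] / n >= 0.01)
}

#' Read the curve at one exposure
#'
#' Returns the mean wall grey at exactly the requested exposure (the
#' reporting convention fixes a constant reference exposure of 2000 ms); no
#' interpolation is performed and an absent exposure is an error listing the
#' available ones.
#'
#' @param curve fluorescence curve from [measureWallIntensity()].
#' @param exposureMs requested exposure (ms).
#' @return the mean grey value at that exposure.
#' @export
intensityAt <- function(curve, exposureMs) {
  i <- which(curve$exposure_ms == exposureMs)
  assertThat(length(i) == 1L,
             "exposure %g ms not in curve; available: %s", exposureMs,
             paste(curve$exposure_ms, collapse = ", "))
  curve$mean_grey[i]
}

#' Write a fluorescence curve as CSV
#'
#' The machine twin of the procedure's "Table of results for fluorescence
#' intensity". Mean grey is written with two decimals, the precision at
#' which wall intensities are conventionally reported.
#'
#' @param curve fluorescence curve from [measureWallIntensity()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path) {
  curve$mean_grey <- sprintf("%.2f", curve$mean_grey)
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
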