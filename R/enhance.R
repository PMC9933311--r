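#' Construct CLAHE parameters
#'
#' @param blockSize pixels per contextual tile edge (odd, >= 3; default 127).
#' @param histogramBins histogram bins per tile (default 256).
#' @param maxSlope clip limit (> 1; default 3).
#' @return a [ClaheParams-class].
#' @export
claheParams <- function(blockSize = 127L, histogramBins = 256L, maxSlope = 3) {
  new("ClaheParams", blockSize = as.integer(blockSize),
      histogramBins = as.integer(histogramBins), maxSlope = as.numeric(maxSlope))
}

#' Contrast-limited adaptive histogram equalization of a frame
#'
#' Normalises the contrast inhomogeneity of wavy sections before
#' thresholding: the image is divided into contextual tiles of roughly
#' `blockSize` pixels, each tile's histogram is clipped at `maxSlope` and
#' equalized, and tile mappings are bilinearly interpolated. Dimensions and
#' calibration are preserved, output stays in \[0, 255\], and the operation
#' is deterministic. A constant image is returned unchanged (no contrast to
#' amplify). The tile-wise equalization is delegated to
#' \code{EBImage::\link[EBImage]{clahe}}; because that routine requires the
#' image extent to be a multiple of the tile count, the frame is padded by
#' edge replication and cropped back.
#'
#' @param image a [GreyImage-class].
#' @param params a [ClaheParams-class]; the block size must be smaller than
#'   the smaller image dimension.
#' @return a [GreyImage-class] of identical dimensions and calibration.
#' @export
claheEnhance <- function(image, params = claheParams()) {
  px <- image@pixels
  nr <- nrow(px); nc <- ncol(px)
  assertThat(params@blockSize < min(nr, nc),
             "blockSize (%d) must be smaller than the smaller image dimension (%d)",
             params@blockSize, min(nr, nc))
  if (min(px) == max(px)) return(image)

  # at least 2 tiles per dimension (the tile-interpolation scheme requires 4
  # contextual regions), otherwise one tile per blockSize of extent
  ny <- max(2L, as.integer(round(nr / params@blockSize)))
  nx <- max(2L, as.integer(round(nc / params@blockSize)))
  prow <- ceiling(nr / ny) * ny
  pcol <- ceiling(nc / nx) * nx
  padded <- px[c(seq_len(nr), rep(nr, prow - nr)),
               c(seq_len(nc), rep(nc, pcol - nc)), drop = FALSE]
  out <- EBImage::clahe(padded / 255, nx = ny, ny = nx,
                        bins = params@histogramBins, limit = params@maxSlope)
  out <- clamp8(roundHalfUp(255 * out[seq_len(nr), seq_len(nc), drop = FALSE]))
  GreyImage(out, image@pixelSizeUm)
}

# apply CLAHE to every frame of a stack
claheStack <- function(stack, params = claheParams()) {
  ExposureStack(lapply(stack@frames, claheEnhance, params = params),
                stack@exposureMs)
}

#' Average intensity projection of a stack
#'
#' Per-pixel arithmetic mean over all frames, rounded half-up, with the
#' calibration preserved. The wall mask of the procedure is thresholded on
#' this projection of the contrast-enhanced stack.
#'
#' @param stack an [ExposureStack-class].
#' @return a [GreyImage-class].
#' @export
averageProjection <- function(stack) {
  acc <- Reduce(`+`, lapply(stack@frames, function(f) f@pixels))
  GreyImage(roundHalfUp(acc / nFrames(stack)), pixelSize(stack))
}
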