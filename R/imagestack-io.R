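#' Construct a GreyImage
#'
#' @param pixels numeric matrix of integer grey levels in \[0, 255\]
#'   (rows = y, columns = x).
#' @param pixelSizeUm micrometres per pixel edge (> 0).
#' @return a [GreyImage-class].
#' @examples
#' img <- GreyImage(matrix(0L, 4, 4), pixelSizeUm = 0.8)
#' @export
GreyImage <- function(pixels, pixelSizeUm) {
  storage.mode(pixels) <- "integer"
  new("GreyImage", pixels = pixels, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Construct an ExposureStack from frames
#'
#' @param frames list of [GreyImage-class] frames (identical dimensions and
#'   calibration).
#' @param exposureMs exposure times in ms, one per frame. Frames are
#'   reordered by ascending exposure.
#' @return an [ExposureStack-class].
#' @export
ExposureStack <- function(frames, exposureMs) {
  exposureMs <- as.numeric(exposureMs)
  assertThat(length(frames) == length(exposureMs),
             "got %d frames but %d exposure times",
             length(frames), length(exposureMs))
  o <- order(exposureMs)
  new("ExposureStack", frames = frames[o], exposureMs = exposureMs[o])
}

#' Convert an RGB image to 8-bit grey
#'
#' The macroscope camera is an 8-bit RGB sensor; the procedure operates on
#' 8-bit grey levels. Conversion is the per-pixel channel mean (rounded
#' half-up) by default; Rec.601 luminance weights are available because the
#' appropriate weighting of an autofluorescence image is a free choice.
#'
#' @param rgb numeric array `height x width x 3` with channel values in
#'   \[0, 255\] (scale [tiff::readTIFF()] output by 255 first).
#' @param pixelSizeUm calibration of the result.
#' @param weights `"mean"` (default, equal weights) or `"luminance"`
#'   (0.299, 0.587, 0.114), or a numeric vector of 3 non-negative weights
#'   which will be normalised to sum to 1.
#' @return a [GreyImage-class].
#' @examples
#' a <- array(c(10, 255, 0, 20, 255, 0, 30, 255, 1), dim = c(1, 3, 3))
#' pixels(toGrey8(a, 0.8))  # 20, 255, 0
#' @export
toGrey8 <- function(rgb, pixelSizeUm, weights = "mean") {
  assertThat(length(dim(rgb)) == 3L && dim(rgb)[3L] == 3L,
             "toGrey8 expects a height x width x 3 array, got dims [%s]",
             paste(dim(rgb), collapse = ", "))
  assertThat(all(rgb >= 0 & rgb <= 255), "channel values must lie in [0, 255]")
  w <- if (identical(weights, "mean")) rep(1 / 3, 3)
       else if (identical(weights, "luminance")) c(0.299, 0.587, 0.114)
       else {
         assertThat(is.numeric(weights) && length(weights) == 3L &&
                    all(weights >= 0) && sum(weights) > 0,
                    "weights must be 'mean', 'luminance' or 3 non-negative numbers")
         weights / sum(weights)
       }
  g <- rgb[, , 1L] * w[1L] + rgb[, , 2L] * w[2L] + rgb[, , 3L] * w[3L]
  g <- matrix(g, dim(rgb)[1L], dim(rgb)[2L])  # guard 1-row dim drop
  GreyImage(clamp8(roundHalfUp(g)), pixelSizeUm)
}

# read one TIFF page (matrix or h x w x 3 array in [0,1]) as a GreyImage
pageToGrey <- function(page, pixelSizeUm, path) {
  if (is.matrix(page)) {
    GreyImage(roundHalfUp(page * 255), pixelSizeUm)
  } else if (length(dim(page)) == 3L && dim(page)[3L] %in% c(3L, 4L)) {
    toGrey8(page[, , 1:3, drop = FALSE] * 255, pixelSizeUm)
  } else {
    stop(sprintf("'%s': unsupported TIFF layout [%s]", path,
                 paste(dim(page), collapse = ", ")), call. = FALSE)
  }
}

# sidecar file path carrying stack metadata next to a TIFF
stackSidecar <- function(path) paste0(sub("\\.tiff?$", "", path), ".stack.yaml")

#' Read a calibrated multi-exposure stack from TIFF files
#'
#' Accepts either several single-frame files (one per exposure) or a single
#' multi-page TIFF. 8-bit grey pages are taken as-is; RGB pages are converted
#' with [toGrey8()]. When a single path is given without exposures, the
#' plain-text sidecar written by [writeStack()] (`<stem>.stack.yaml`) supplies
#' exposure times and pixel size.
#'
#' @param paths character vector of TIFF paths.
#' @param exposuresMs exposure times in ms, one per frame (or `NULL` to read
#'   them from the sidecar of a single multi-page file).
#' @param pixelSizeUm micrometres per pixel (or `NULL` with a sidecar).
#' @return an [ExposureStack-class] with frames ordered by ascending exposure.
#' @seealso [writeStack()]
#' @export
readStack <- function(paths, exposuresMs = NULL, pixelSizeUm = NULL) {
  assertThat(length(paths) >= 1L, "at least one path is required")
  for (p in paths)
    assertThat(file.exists(p), "file not found: '%s'", p)

  if (length(paths) == 1L && (is.null(exposuresMs) || is.null(pixelSizeUm))) {
    sc <- stackSidecar(paths)
    assertThat(file.exists(sc),
               "no exposures given and no sidecar found for '%s' (expected '%s')",
               paths, sc)
    meta <- yaml::read_yaml(sc)
    if (is.null(exposuresMs)) exposuresMs <- as.numeric(meta$exposures_ms)
    if (is.null(pixelSizeUm)) pixelSizeUm <- as.numeric(meta$pixel_size_um)
  }
  assertThat(!is.null(exposuresMs) && !is.null(pixelSizeUm),
             "exposuresMs and pixelSizeUm are required for multi-file stacks")

  pages <- list()
  for (p in paths) {
    pg <- tryCatch(tiff::readTIFF(p, all = TRUE),
                   error = function(e)
                     stop(sprintf("cannot read '%s': %s", p, conditionMessage(e)),
                          call. = FALSE))
    pages <- c(pages, lapply(pg, pageToGrey, pixelSizeUm = pixelSizeUm, path = p))
  }
  assertThat(length(pages) == length(exposuresMs),
             "%d frames decoded but %d exposure times given",
             length(pages), length(exposuresMs))
  d1 <- dim(pages[[1L]]@pixels)
  for (i in seq_along(pages))
    assertThat(identical(dim(pages[[i]]@pixels), d1),
               "frame %d (from '%s') has dimensions %s, expected %s", i,
               paths[min(i, length(paths))],
               paste(dim(pages[[i]]@pixels), collapse = "x"),
               paste(d1, collapse = "x"))
  ExposureStack(pages, exposuresMs)
}

#' Write a stack as a multi-page TIFF plus plain-text metadata sidecar
#'
#' One uncompressed 8-bit grey page per frame, in ascending-exposure order.
#' Exposure times and pixel size are stored in a YAML sidecar
#' (`<stem>.stack.yaml`) next to the image so that
#' `readStack(writeStack(s))` reproduces the stack bit-exactly.
#'
#' @param stack an [ExposureStack-class].
#' @param path destination TIFF path.
#' @return `path`, invisibly.
#' @seealso [readStack()]
#' @export
writeStack <- function(stack, path) {
  mats <- lapply(stack@frames, function(f) f@pixels / 255)
  ok <- tryCatch(
    tiff::writeTIFF(mats, path, bits.per.sample = 8L,
                    compression = "none", reduce = FALSE),
    error = function(e)
      stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
           call. = FALSE))
  yaml::write_yaml(
    list(exposures_ms = as.numeric(stack@exposureMs),
         pixel_size_um = pixelSize(stack),
         frames = nFrames(stack)),
    stackSidecar(path))
  invisible(path)
}

#' Grey-level histogram of an image
#'
#' @param image a [GreyImage-class].
#' @param mask optional logical matrix of the same dimensions; when given,
#'   only `TRUE` pixels are counted.
#' @return an [IntensityHistogram-class] with 256 bins.
#' @examples
#' h <- computeHistogram(GreyImage(matrix(c(0, 0, 255, 255), 2, 2), 1))
#' histCounts(h)[c(1, 256)]
#' @export
computeHistogram <- function(image, mask = NULL) {
  px <- image@pixels
  if (!is.null(mask)) {
    assertThat(is.logical(mask) && identical(dim(mask), dim(px)),
               "mask must be a logical matrix matching the image dimensions")
    px <- px[mask]
    assertThat(length(px) > 0L, "mask selects zero pixels")
  }
  counts <- tabulate(as.integer(px) + 1L, nbins = 256L)
  new("IntensityHistogram", counts = as.numeric(counts), total = sum(counts))
}

#' Parse an exposure time from a file name
#'
#' Convenience only: exposure metadata is normally carried explicitly.
#' Extracts the first integer followed by "ms" (case-insensitive), e.g.
#' `"section3_1200ms.tif"` gives 1200.
#'
#' @param filenames character vector.
#' @return numeric vector of exposures (ms); `NA` where no pattern matched.
#' @export
exposureFromFilename <- function(filenames) {
  m <- regmatches(filenames,
                  regexpr("[0-9]+(?=[[:space:]_-]?ms)", filenames,
                          perl = TRUE, ignore.case = TRUE))
  out <- rep(NA_real_, length(filenames))
  hit <- vapply(filenames, function(f)
    grepl("[0-9]+[[:space:]_-]?ms", f, ignore.case = TRUE), TRUE)
  out[hit] <- as.numeric(m)
  out
}
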