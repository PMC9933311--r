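#' Accessors for the core classes
#'
#' `pixels()` returns the integer grey-level matrix of a [GreyImage-class];
#' `pixelSize()` its calibration in micrometres per pixel. `frames()` returns
#' the list of frames of an [ExposureStack-class], `exposureTimes()` its
#' exposure series in ms and `nFrames()` the frame count. `histCounts()`
#' returns the 256 counts of an [IntensityHistogram-class] and
#' `thresholdLevel()` the integer level of a [ThresholdResult-class].
#'
#' @param object the object to access.
#' @return the slot value described above.
#' @name accessors
#' @examples
#' img <- GreyImage(matrix(0:3, 2, 2), pixelSizeUm = 0.8)
#' pixels(img)
#' pixelSize(img)
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "GreyImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "GreyImage", function(object) object@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ExposureStack",
          function(object) object@frames[[1L]]@pixelSizeUm)

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "ExposureStack", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("exposureTimes", function(object) standardGeneric("exposureTimes"))
#' @rdname accessors
#' @export
setMethod("exposureTimes", "ExposureStack", function(object) object@exposureMs)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "ExposureStack", function(object) length(object@frames))

#' @rdname accessors
#' @export
setGeneric("histCounts", function(object) standardGeneric("histCounts"))
#' @rdname accessors
#' @export
setMethod("histCounts", "IntensityHistogram", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("thresholdLevel", function(object) standardGeneric("thresholdLevel"))
#' @rdname accessors
#' @export
setMethod("thresholdLevel", "ThresholdResult", function(object) object@level)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "SectionTruth", function(object) object@lumens)

#' @rdname accessors
#' @export
setGeneric("trueWallCurve", function(object) standardGeneric("trueWallCurve"))
#' @rdname accessors
#' @export
setMethod("trueWallCurve", "SectionTruth", function(object) object@wallCurve)

#' @rdname accessors
#' @export
setGeneric("trueWallMask", function(object) standardGeneric("trueWallMask"))
#' @rdname accessors
#' @export
setMethod("trueWallMask", "SectionTruth", function(object) object@wallMask)
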