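#' Accessors for StereoHOG objects
#'
#' Slot accessors for the S4 containers: images of a \code{StereoPair},
#' ground truth and masks of a \code{SyntheticScene}, the cost array and
#' maximum disparity of a \code{CostVolume}, the disparity and validity of a
#' \code{DisparityMap}, and the descriptor arrays of a
#' \code{DescriptorField}.
#'
#' @param x the object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("baseImage", "StereoPair", function(x) x@base)
#' @rdname accessors
#' @export
setMethod("baseImage", "SyntheticScene", function(x) x@baseImage)
#' @rdname accessors
#' @export
setMethod("matchingImage", "StereoPair", function(x) x@matching)
#' @rdname accessors
#' @export
setMethod("gtDisparity", "SyntheticScene", function(x) x@gtDisparity)
#' @rdname accessors
#' @export
setMethod("occlusionMask", "SyntheticScene", function(x) x@occlusionMask)
#' @rdname accessors
#' @export
setMethod("textureMask", "SyntheticScene", function(x) x@textureMask)
#' @rdname accessors
#' @export
setMethod("costs", "CostVolume", function(x) x@costs)
#' @rdname accessors
#' @export
setMethod("dmax", "CostVolume", function(x) x@dmax)
#' @rdname accessors
#' @export
setMethod("dmax", "DisparityMap", function(x) x@dmax)
#' @rdname accessors
#' @export
setMethod("dmax", "SyntheticScene", function(x) x@dmax)
#' @rdname accessors
#' @export
setMethod("validMask", "CostVolume", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("validMask", "DisparityMap", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("validMask", "DescriptorField", function(x) x@validMask)
#' @rdname accessors
#' @export
setMethod("disparity", "DisparityMap", function(x) x@disparity)
#' @rdname accessors
#' @export
setMethod("angleHist", "DescriptorField", function(x) x@angleHist)
#' @rdname accessors
#' @export
setMethod("ampVec", "DescriptorField", function(x) x@ampVec)

setMethod("show", "StereoPair", function(object) {
  d <- dim(object@base)
  cat(sprintf("StereoPair: %d x %d, intensity range [%.1f, %.1f]%s\n",
              d[1], d[2], min(object@base, object@matching),
              max(object@base, object@matching),
              if (is.null(object@baseColor)) "" else ", with colour"))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene: %d x %d, dmax = %d, %.1f%% occluded, %.1f%% textured\n",
    nrow(object@baseImage), ncol(object@baseImage), object@dmax,
    100 * mean(!object@occlusionMask), 100 * mean(object@textureMask)))
})

setMethod("show", "CostVolume", function(object) {
  d <- dim(object@costs)
  cat(sprintf(
    "CostVolume: %d x %d x %d (dmax = %d), %.1f%% valid, cost range [%.3g, %.3g]\n",
    d[1], d[2], d[3], object@dmax, 100 * mean(object@valid),
    min(object@costs), max(object@costs)))
})

setMethod("show", "DisparityMap", function(object) {
  v <- object@disparity[object@valid]
  cat(sprintf("DisparityMap: %d x %d (dmax = %d), %.1f%% valid%s\n",
              nrow(object@disparity), ncol(object@disparity), object@dmax,
              100 * mean(object@valid),
              if (length(v)) sprintf(", disparities in [%g, %g]",
                                     min(v), max(v)) else ""))
})

setMethod("show", "DescriptorField", function(object) {
  cat(sprintf(
    "DescriptorField: %d x %d, %d angle bins, amplitude length %d, %s window\n",
    dim(object@angleHist)[1], dim(object@angleHist)[2],
    dim(object@angleHist)[3], dim(object@ampVec)[3],
    if (is.null(object@masks)) "fixed" else "adaptive"))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf(
    "QualityReport (n = %d): bad1.0 = %.2f%%, bad2.0 = %.2f%%, invalid = %.2f%%, totBad = %.2f%%, avgErr = %.3f px\n",
    object@nEval, object@bad1_0, object@bad2_0, object@invalidPct,
    object@totBad, object@avgErr))
})

#' Convert a QualityReport to a named list
#'
#' @param x a \code{QualityReport}.
#' @param ... unused.
#' @return named list with elements bad1_0, bad2_0, invalid, totBad,
#'   avgErr, nEval.
#' @export
setMethod("as.list", "QualityReport", function(x, ...) {
  list(bad1_0 = x@bad1_0, bad2_0 = x@bad2_0, invalid = x@invalidPct,
       totBad = x@totBad, avgErr = x@avgErr, nEval = x@nEval)
})
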