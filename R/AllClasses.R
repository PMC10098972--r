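#' @import methods
NULL

#' Rectified stereo image pair
#'
#' Container for a rectified stereo pair. The \code{base} (left) image is the
#' one whose pixels receive disparities; the corresponding pixel of base pixel
#' \eqn{(x, y)} at disparity \eqn{d} lies at \eqn{(x - d, y)} in the
#' \code{matching} (right) image. Images are stored as numeric matrices in
#' intensity units [0, 255], rows indexing the vertical (y) axis and columns
#' the horizontal (x) axis. Optional full-colour versions are kept only for
#' the adaptive-window colour threshold; all descriptors are computed on the
#' grayscale channels.
#'
#' @slot base numeric matrix, left image.
#' @slot matching numeric matrix, right image, same dimensions.
#' @slot baseColor optional H x W x 3 array or NULL.
#' @slot matchingColor optional H x W x 3 array or NULL.
#' @export
setClass("StereoPair",
  representation(base = "matrix", matching = "matrix",
                 baseColor = "ANY", matchingColor = "ANY"),
  prototype(baseColor = NULL, matchingColor = NULL),
  validity = function(object) {
    if (!all(dim(object@base) == dim(object@matching)))
      return("base and matching images must have identical dimensions")
    if (!is.numeric(object@base) || !is.numeric(object@matching))
      return("images must be numeric matrices")
    for (s in c("baseColor", "matchingColor")) {
      cc <- slot(object, s)
      if (!is.null(cc)) {
        if (length(dim(cc)) != 3L || dim(cc)[3] != 3L ||
            !all(dim(cc)[1:2] == dim(object@base)))
          return(sprintf("%s must be NULL or an H x W x 3 array", s))
      }
    }
    TRUE
  })

#' Synthetic stereo scene with exact ground truth
#'
#' A generated scene: a base image, a piecewise-constant ground-truth
#' disparity field, the visibility (non-occlusion) mask implied by forward
#' warping the base image into the matching view, and labels separating
#' textured from homogeneous regions.
#'
#' @slot baseImage numeric matrix in [0, 255].
#' @slot gtDisparity numeric matrix of non-negative integer disparities.
#' @slot occlusionMask logical matrix; TRUE where the pixel is visible in
#'   both views (not occluded, warp target in bounds).
#' @slot textureMask logical matrix; TRUE for textured pixels, FALSE in
#'   homogeneous regions.
#' @slot dmax integer, maximum disparity the scene was built for.
#' @export
setClass("SyntheticScene",
  representation(baseImage = "matrix", gtDisparity = "matrix",
                 occlusionMask = "matrix", textureMask = "matrix",
                 dmax = "integer"),
  validity = function(object) {
    d <- dim(object@baseImage)
    if (!all(dim(object@gtDisparity) == d) ||
        !all(dim(object@occlusionMask) == d) ||
        !all(dim(object@textureMask) == d))
      return("all scene fields must share the base image dimensions")
    if (!is.logical(object@occlusionMask) || !is.logical(object@textureMask))
      return("occlusionMask and textureMask must be logical matrices")
    if (any(object@gtDisparity < 0) || any(object@gtDisparity > object@dmax))
      return("gtDisparity must lie in [0, dmax]")
    TRUE
  })

#' Per-pixel HOG descriptor fields
#'
#' Dense fields of the two radiometric-invariant descriptors: the normalized
#' gradient-angle histogram (\code{angleHist}, H x W x nBins) and the
#' window-concatenated relative gradient amplitude vector (\code{ampVec},
#' H x W x L). Border pixels whose window leaves the image are flagged
#' invalid. Pixels whose centre gradient vanishes get an all-zero amplitude
#' descriptor and are flagged in \code{ampFlagged}; their amplitude cost is
#' taken as the neutral value 1 so matching is driven by the angle term.
#'
#' @slot angleHist numeric array H x W x nBins; each pixel's vector sums to
#'   1 or is all zero.
#' @slot ampVec numeric array H x W x L (L = window^2 positional layout, or
#'   nBins for the angular-accumulation layout); L1-normalized or all zero.
#' @slot validMask logical matrix, FALSE on the border margin.
#' @slot ampFlagged logical matrix, TRUE where the centre gradient is ~0.
#' @slot masks NULL, or logical H x W x window^2 adaptive-window masks
#'   (raster order over the window) computed from this image.
#' @slot config list, the \code{\link{hogWindowConfig}} used.
#' @export
setClass("DescriptorField",
  representation(angleHist = "array", ampVec = "array",
                 validMask = "matrix", ampFlagged = "matrix",
                 masks = "ANY", config = "list"),
  prototype(masks = NULL),
  validity = function(object) {
    d <- dim(object@angleHist)[1:2]
    if (!all(dim(object@ampVec)[1:2] == d) ||
        !all(dim(object@validMask) == d) || !all(dim(object@ampFlagged) == d))
      return("descriptor arrays must share H x W dimensions")
    TRUE
  })

#' Stereo matching cost volume
#'
#' H x W x (dmax + 1) array of matching costs C(x, y, d), smaller = more
#' similar, with slice d + 1 holding disparity d. \code{valid} is FALSE where
#' the candidate match x - d falls outside the matching image interior (or
#' the base pixel itself sits on the border); those entries are filled with
#' the per-pixel maximum valid cost so that filtering does not bleed an
#' arbitrary sentinel.
#'
#' @slot costs numeric array H x W x (dmax + 1), non-negative.
#' @slot valid logical array of the same shape.
#' @slot dmax integer maximum disparity.
#' @export
setClass("CostVolume",
  representation(costs = "array", valid = "array", dmax = "integer"),
  validity = function(object) {
    dc <- dim(object@costs)
    if (length(dc) != 3L) return("costs must be a 3-d array")
    if (!all(dim(object@valid) == dc)) return("valid must match costs shape")
    if (dc[3] != object@dmax + 1L)
      return("third dimension must equal dmax + 1")
    if (any(object@costs < 0)) return("costs must be non-negative")
    TRUE
  })

#' Disparity map with validity mask
#'
#' Per-pixel integer disparities plus a validity mask recording border,
#' no-valid-candidate and (after \code{\link{lrcCheck}}) left-right
#' consistency failures.
#'
#' @slot disparity numeric matrix of disparities in pixels.
#' @slot valid logical matrix.
#' @slot dmax integer maximum disparity.
#' @export
setClass("DisparityMap",
  representation(disparity = "matrix", valid = "matrix", dmax = "integer"),
  validity = function(object) {
    if (!all(dim(object@disparity) == dim(object@valid)))
      return("disparity and valid must have equal dimensions")
    if (!is.logical(object@valid)) return("valid must be logical")
    v <- object@disparity[object@valid]
    if (length(v) && (any(v < 0) || any(v > object@dmax)))
      return("valid disparities must lie in [0, dmax]")
    TRUE
  })

#' Middlebury-style disparity quality report
#'
#' Percentages of bad pixels at the 1.0 and 2.0 px thresholds, the
#' percentage of pixels failing the left-right consistency check
#' (\code{invalidPct}), their sum \code{totBad = bad1_0 + invalidPct}, and
#' the mean absolute disparity error in pixels over the assessed valid
#' pixels. Fields are NaN when the evaluation mask selects no pixel.
#'
#' @slot bad1_0 numeric, percent of assessed valid pixels with error > 1 px.
#' @slot bad2_0 numeric, percent with error > 2 px.
#' @slot invalidPct numeric, percent of assessed pixels that are invalid.
#' @slot totBad numeric, bad1_0 + invalidPct.
#' @slot avgErr numeric, mean absolute error (px) over assessed valid pixels.
#' @slot nEval integer, number of assessed pixels.
#' @export
setClass("QualityReport",
  representation(bad1_0 = "numeric", bad2_0 = "numeric",
                 invalidPct = "numeric", totBad = "numeric",
                 avgErr = "numeric", nEval = "integer"))
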