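#' @rdname accessors
#' @export
setGeneric("baseImage", function(x) standardGeneric("baseImage"))
#' @rdname accessors
#' @export
setGeneric("matchingImage", function(x) standardGeneric("matchingImage"))
#' @rdname accessors
#' @export
setGeneric("gtDisparity", function(x) standardGeneric("gtDisparity"))
#' @rdname accessors
#' @export
setGeneric("occlusionMask", function(x) standardGeneric("occlusionMask"))
#' @rdname accessors
#' @export
setGeneric("textureMask", function(x) standardGeneric("textureMask"))
#' @rdname accessors
#' @export
setGeneric("costs", function(x) standardGeneric("costs"))
#' @rdname accessors
#' @export
setGeneric("dmax", function(x) standardGeneric("dmax"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("disparity", function(x) standardGeneric("disparity"))
#' @rdname accessors
#' @export
setGeneric("angleHist", function(x) standardGeneric("angleHist"))
#' @rdname accessors
#' @export
setGeneric("ampVec", function(x) standardGeneric("ampVec"))
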