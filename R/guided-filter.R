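# Guided image filtering of cost-volume slices. The filter assumes the
# output is an affine function of the guide inside each window — the same
# local linear model the HOG metrics rely on, which is why it denoises the
# cost volume without smearing costs across intensity edges.

#' Guided image filter
#'
#' Edge-preserving filter of \code{input} steered by \code{guide}: within
#' every (2 radius + 1)^2 window k an affine model
#' \code{q = a_k * guide + b_k} is fitted
#' (\code{a_k = cov(guide, input) / (var(guide) + eps)},
#' \code{b_k = mean(input) - a_k mean(guide)}) and each pixel's output
#' averages the models of all windows containing it. Windows shrink at the
#' image border (normalized box counts). Exact box-filter implementation;
#' O(H W) regardless of radius.
#'
#' @param input numeric H x W matrix to be filtered.
#' @param guide numeric H x W matrix, expected on a [0, 1] scale (use
#'   \code{\link{normalizeGuide}}); \code{eps} is in its squared units.
#' @param cfg a \code{\link{guidedFilterConfig}}.
#' @return filtered numeric H x W matrix.
#' @examples
#' x <- matrix(rnorm(64 * 64), 64)
#' g <- normalizeGuide(matrix(runif(64 * 64, 0, 255), 64))
#' q <- guidedFilter(x, g)
#' @export
guidedFilter <- function(input, guide, cfg = guidedFilterConfig()) {
  if (!all(dim(input) == dim(guide)))
    stop("input and guide must have identical dimensions")
  r <- cfg$radius; eps <- cfg$eps
  mI <- .boxMean(guide, r)
  mP <- .boxMean(input, r)
  corrI <- .boxMean(guide * guide, r)
  corrIP <- .boxMean(guide * input, r)
  varI <- corrI - mI * mI
  covIP <- corrIP - mI * mP
  a <- covIP / (varI + eps)
  b <- mP - a * mI
  .boxMean(a, r) * guide + .boxMean(b, r)
}

#' Normalize a guide image to [0, 1]
#'
#' Min-max normalization. Because the map is affine, a linear radiometric
#' distortion \code{c * g + t} of the guide (without clipping) yields the
#' identical normalized guide, so guided filtering of the cost volume is
#' exactly as invariant as the costs themselves.
#'
#' @param image numeric matrix.
#' @return matrix rescaled to [0, 1]; a constant image maps to all zeros.
#' @export
normalizeGuide <- function(image) {
  rng <- range(image)
  if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
  else matrix(0, nrow(image), ncol(image))
}

#' Filter a cost volume slice-wise with the guided filter
#'
#' Slices the volume along the disparity dimension, filters every slice
#' with the same guide image, and reassembles. The validity mask is
#' unchanged; tiny filter undershoots below zero are clamped so costs stay
#' non-negative.
#'
#' @param cv a \code{\linkS4class{CostVolume}}.
#' @param guide grayscale image of the same H x W (any intensity scale; it
#'   is min-max normalized internally).
#' @param cfg a \code{\link{guidedFilterConfig}}.
#' @return A \code{\linkS4class{CostVolume}}.
#' @export
filterCostVolume <- function(cv, guide, cfg = guidedFilterConfig()) {
  guide <- normalizeGuide(.luma(guide))
  if (!all(dim(guide) == dim(cv@costs)[1:2]))
    stop("guide must match the volume's H x W")
  out <- cv@costs
  for (d in seq_len(dim(out)[3]))
    out[, , d] <- pmax(guidedFilter(cv@costs[, , d], guide, cfg), 0)
  new("CostVolume", costs = out, valid = cv@valid, dmax = cv@dmax)
}
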