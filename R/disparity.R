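# WTA disparity extraction, left-right consistency checking and
# Middlebury-style quality metrics.

#' Winner-takes-all disparity extraction
#'
#' Per pixel, the disparity with minimum cost among the valid candidates;
#' ties break toward the smaller disparity. Pixels with no valid candidate
#' are marked invalid.
#'
#' @param cv a \code{\linkS4class{CostVolume}}.
#' @return A \code{\linkS4class{DisparityMap}}.
#' @examples
#' sc <- makeScene(48, 64, dmax = 4, seed = 1)
#' pr <- renderMatchingImage(sc)
#' dm <- wta(hogCostVolume(pr, dmax = 4))
#' dm
#' @export
wta <- function(cv) {
  H <- dim(cv@costs)[1]; W <- dim(cv@costs)[2]; D <- dim(cv@costs)[3]
  cm <- matrix(cv@costs, H * W, D)
  vm <- matrix(cv@valid, H * W, D)
  cm[!vm] <- Inf
  best <- max.col(-cm, ties.method = "first") - 1L
  ok <- rowSums(vm) > 0
  best[!ok] <- 0L
  new("DisparityMap", disparity = matrix(as.numeric(best), H, W),
      valid = matrix(ok, H, W), dmax = cv@dmax)
}

#' Left-right consistency check
#'
#' Marks a base-image pixel valid only if its disparity is confirmed by the
#' right-image disparity map: \code{|dL(x, y) - dR(x - dL(x, y), y)| <= tol}
#' with the looked-up pixel in bounds and valid in both maps. Failures are
#' mostly occlusions and mismatches.
#'
#' @param dLeft disparity map of the base (left) image.
#' @param dRight disparity map computed with the images' roles swapped
#'   (see \code{\link{computeDisparity}} with \code{side = "right"}).
#' @param tol tolerance in pixels (default 1).
#' @return \code{dLeft} with its validity mask tightened.
#' @export
lrcCheck <- function(dLeft, dRight, tol = 1) {
  dl <- dLeft@disparity
  H <- nrow(dl); W <- ncol(dl)
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  xr <- xs - round(dl)
  inb <- xr >= 1 & xr <= W
  xr[!inb] <- 1L
  idx <- cbind(as.vector(row(dl)), as.vector(xr))
  dr <- matrix(dRight@disparity[idx], H, W)
  vr <- matrix(dRight@valid[idx], H, W)
  ok <- dLeft@valid & inb & vr & abs(dl - dr) <= tol
  new("DisparityMap", disparity = dl, valid = ok, dmax = dLeft@dmax)
}

#' Middlebury-style disparity quality metrics
#'
#' Computes, over the pixels selected by \code{evalMask}: the percentage of
#' valid pixels with absolute error above 1.0 px (\code{bad1_0}) and 2.0 px
#' (\code{bad2_0}), the percentage of selected pixels that are invalid
#' (failed LRC / border / no candidate), their sum
#' \code{totBad = bad1_0 + invalid}, and the mean absolute error in pixels
#' over the valid selected pixels. With \code{allPixels = TRUE} the
#' validity mask is ignored and every selected pixel enters the error
#' statistics (Middlebury "all"-style accounting; \code{invalid} is then 0
#' by construction in the bad/avg terms but still reported from the mask).
#'
#' @param d a \code{\linkS4class{DisparityMap}}.
#' @param gt numeric ground-truth disparity matrix.
#' @param evalMask logical matrix of assessed pixels (e.g. non-occluded);
#'   default all.
#' @param allPixels logical, include invalid pixels in the error stats.
#' @return A \code{\linkS4class{QualityReport}}; fields are NaN when
#'   \code{evalMask} selects nothing.
#' @examples
#' gt <- matrix(0, 8, 8)
#' dm <- new("DisparityMap", disparity = gt, valid = matrix(TRUE, 8, 8),
#'           dmax = 4L)
#' evaluateDisparity(dm, gt)
#' @export
evaluateDisparity <- function(d, gt, evalMask = NULL, allPixels = FALSE) {
  dm <- d@disparity
  if (!all(dim(gt) == dim(dm))) stop("ground truth shape mismatch")
  if (is.null(evalMask)) evalMask <- matrix(TRUE, nrow(dm), ncol(dm))
  if (!all(dim(evalMask) == dim(dm))) stop("evalMask shape mismatch")
  nEval <- sum(evalMask)
  if (nEval == 0)
    return(new("QualityReport", bad1_0 = NaN, bad2_0 = NaN,
               invalidPct = NaN, totBad = NaN, avgErr = NaN, nEval = 0L))
  use <- if (allPixels) evalMask else evalMask & d@valid
  err <- abs(dm - gt)[use]
  nUse <- sum(use)
  bad1 <- if (nUse) 100 * mean(err > 1.0) else NaN
  bad2 <- if (nUse) 100 * mean(err > 2.0) else NaN
  avg <- if (nUse) mean(err) else NaN
  inv <- 100 * sum(evalMask & !d@valid) / nEval
  new("QualityReport", bad1_0 = bad1, bad2_0 = bad2, invalidPct = inv,
      totBad = bad1 + inv, avgErr = avg, nEval = as.integer(nEval))
}
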