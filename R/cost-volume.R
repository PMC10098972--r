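# Initial cost volume from the descriptor fields: per pixel and candidate
# disparity, the L1 distance between the base descriptor at (x, y) and the
# matching descriptor at (x - d, y), with the angle and amplitude metrics
# average-fused.

#' L1 descriptor cost
#'
#' Sum of absolute bin differences between two descriptor vectors; for
#' L1-normalized descriptors the cost lies in [0, 2].
#'
#' @param descB,descM equal-length numeric vectors.
#' @return non-negative scalar.
#' @examples
#' descriptorCost(c(1, 0, 0), c(0, 0.5, 0.5))
#' @export
descriptorCost <- function(descB, descM) {
  if (length(descB) != length(descM))
    stop("descriptor vectors must have equal length")
  sum(abs(descB - descM))
}

.logicalShift <- function(M, dy, dx) .shift(M * 1, dy, dx) > 0

# fill invalid entries of a cost array with the per-pixel maximum valid
# cost, so neither WTA nor filtering is driven by an arbitrary sentinel
.fillInvalid <- function(costs, valid) {
  H <- dim(costs)[1]; W <- dim(costs)[2]; D <- dim(costs)[3]
  cm <- matrix(costs, H * W, D)
  vm <- matrix(valid, H * W, D)
  tmp <- cm
  tmp[!vm] <- -Inf
  mx <- do.call(pmax, c(as.data.frame(tmp), list(na.rm = TRUE)))
  mx[!is.finite(mx)] <- 0
  cm[!vm] <- rep(mx, times = D)[!vm]
  array(cm, c(H, W, D))
}

#' Initial HOG cost volume from precomputed descriptor fields
#'
#' Builds the H x W x (dmax + 1) cost volume from fixed-window descriptor
#' fields of the base and matching images: slice d holds the L1 descriptor
#' distance between base pixel (x, y) and matching pixel (x - d, y). The
#' angle and amplitude cost volumes are fused as
#' \code{w * C_angle + (1 - w) * C_amplitude}; \code{fusionRatio = 0.5} is
#' the 1:1 fusion. Where either window centre has a vanishing gradient the
#' amplitude metric is undefined and its cost is the neutral value 1.
#' Entries whose match falls outside the matching-image interior are
#' invalid and filled with the per-pixel maximum valid cost.
#'
#' @param descBase,descMatch \code{\linkS4class{DescriptorField}}s of the
#'   two images (same size, same configuration).
#' @param dmax integer maximum disparity, < image width.
#' @param fusionRatio weight of the angle metric in (0, 1), or the metric
#'   selector below.
#' @param metric \code{"fused"}, \code{"angle"} or \code{"amplitude"}.
#' @return A \code{\linkS4class{CostVolume}}.
#' @examples
#' sc <- makeScene(48, 64, dmax = 4, layout = "single-plane", seed = 1)
#' pr <- renderMatchingImage(sc)
#' cfg <- hogWindowConfig()
#' cv <- buildInitialCostVolume(buildDescriptorFields(baseImage(pr), cfg),
#'                              buildDescriptorFields(matchingImage(pr), cfg),
#'                              dmax = 4)
#' cv
#' @export
buildInitialCostVolume <- function(descBase, descMatch, dmax,
                                   fusionRatio = 0.5,
                                   metric = c("fused", "angle", "amplitude")) {
  metric <- match.arg(metric)
  Ab <- descBase@angleHist; Am <- descMatch@angleHist
  Vb <- descBase@ampVec; Vm <- descMatch@ampVec
  H <- dim(Ab)[1]; W <- dim(Ab)[2]
  dmax <- as.integer(dmax)
  if (dmax >= W) stop("dmax must be smaller than the image width")
  if (!all(dim(Am) == dim(Ab)) || !all(dim(Vm) == dim(Vb)))
    stop("descriptor fields must come from same-size images")
  nb <- dim(Ab)[3]; L <- dim(Vb)[3]
  w <- fusionRatio

  costs <- array(0, c(H, W, dmax + 1L))
  valid <- array(FALSE, c(H, W, dmax + 1L))
  for (d in 0:dmax) {
    ca <- matrix(0, H, W); cv <- matrix(0, H, W)
    if (metric != "amplitude")
      for (b in seq_len(nb))
        ca <- ca + abs(Ab[, , b] - .shift(Am[, , b], 0L, -d))
    if (metric != "angle") {
      for (l in seq_len(L))
        cv <- cv + abs(Vb[, , l] - .shift(Vm[, , l], 0L, -d))
      und <- descBase@ampFlagged | .logicalShift(descMatch@ampFlagged, 0L, -d)
      cv[und] <- 1
    }
    costs[, , d + 1L] <- switch(metric, fused = w * ca + (1 - w) * cv,
                                angle = ca, amplitude = cv)
    valid[, , d + 1L] <- descBase@validMask &
      .logicalShift(descMatch@validMask, 0L, -d)
  }
  new("CostVolume", costs = .fillInvalid(costs, valid), valid = valid,
      dmax = dmax)
}

#' HOG cost volume of a stereo pair
#'
#' End-to-end initial cost volume construction from a
#' \code{\linkS4class{StereoPair}}. With fixed windows the two descriptor
#' fields are computed once and slid against each other. With
#' \code{adaptive = TRUE} the window masks are derived from the base image
#' and travel with the base pixel: at every candidate disparity d the
#' matching-image descriptors are re-evaluated at (x - d, y) under the mask
#' of base pixel (x, y), which is what makes the adaptive window suppress
#' high-gradient outliers consistently in both views.
#'
#' @param pair a \code{\linkS4class{StereoPair}}.
#' @param dmax integer maximum disparity.
#' @param cfg a \code{\link{hogWindowConfig}}.
#' @param fusionRatio angle-metric weight in (0, 1).
#' @param metric \code{"fused"}, \code{"angle"} or \code{"amplitude"}.
#' @param adaptive logical, overrides \code{cfg$adaptive}.
#' @return A \code{\linkS4class{CostVolume}}.
#' @export
hogCostVolume <- function(pair, dmax, cfg = hogWindowConfig(),
                          fusionRatio = 0.5,
                          metric = c("fused", "angle", "amplitude"),
                          adaptive = cfg$adaptive) {
  metric <- match.arg(metric)
  if (!isTRUE(adaptive)) {
    return(buildInitialCostVolume(
      buildDescriptorFields(pair@base, cfg, adaptive = FALSE),
      buildDescriptorFields(pair@matching, cfg, adaptive = FALSE),
      dmax, fusionRatio, metric))
  }
  grayB <- .luma(pair@base); grayM <- .luma(pair@matching)
  H <- nrow(grayB); W <- ncol(grayB)
  dmax <- as.integer(dmax)
  if (dmax >= W) stop("dmax must be smaller than the image width")
  gB <- computeGradients(grayB, cfg$gradientOperator)
  imgForColor <- if (is.null(pair@baseColor)) grayB else pair@baseColor
  masks <- .adaptiveMasks(imgForColor, sqrt(gB$gx^2 + gB$gy^2), cfg)
  db <- .denseDescriptors(grayB, cfg, masks = masks)
  w <- fusionRatio

  costs <- array(0, c(H, W, dmax + 1L))
  valid <- array(FALSE, c(H, W, dmax + 1L))
  nb <- cfg$nBins
  L <- dim(db$ampVec)[3]
  for (d in 0:dmax) {
    dm <- .denseDescriptors(grayM, cfg, masks = masks, dxShift = -d)
    ca <- matrix(0, H, W); cv <- matrix(0, H, W)
    if (metric != "amplitude")
      for (b in seq_len(nb))
        ca <- ca + abs(db$angleHist[, , b] - dm$angleHist[, , b])
    if (metric != "angle") {
      for (l in seq_len(L))
        cv <- cv + abs(db$ampVec[, , l] - dm$ampVec[, , l])
      cv[db$ampFlagged | dm$ampFlagged] <- 1
    }
    costs[, , d + 1L] <- switch(metric, fused = w * ca + (1 - w) * cv,
                                angle = ca, amplitude = cv)
    valid[, , d + 1L] <- db$validMask & .logicalShift(db$validMask, 0L, -d)
  }
  new("CostVolume", costs = .fillInvalid(costs, valid), valid = valid,
      dmax = dmax)
}
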