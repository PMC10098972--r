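# HOG angle / relative HOG amplitude descriptor fields. Both descriptors
# are invariant under the linear radiometric model g' = c*g + t (c > 0):
# gradients kill t, and the angle (a direction) and the relative amplitude
# (a ratio) both cancel c.

.EPS_AMP <- 1e-6

#' Image gradients
#'
#' Horizontal and vertical gradients of a single-channel image. The default
#' operator is central differences (kernel [-1, 0, 1] / 2) in the interior
#' with one-sided differences on the border rows/columns; central
#' differences are exactly linear in the image, which preserves the
#' radiometric-invariance argument without discretization slack. A Sobel
#' operator (normalized by 8) is available as an alternative.
#'
#' @param image numeric H x W matrix (convert RGB with its ITU-R 601 luma
#'   first).
#' @param operator \code{"central"} or \code{"sobel"}.
#' @return list with matrices \code{gx} (d/dx) and \code{gy} (d/dy).
#' @examples
#' g <- computeGradients(outer(1:5, 1:6, function(y, x) 3 * x))
#' g$gx[3, 3]
#' @export
computeGradients <- function(image, operator = c("central", "sobel")) {
  operator <- match.arg(operator)
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric H x W matrix")
  H <- nrow(image); W <- ncol(image)
  if (operator == "central") {
    gx <- (.shift(image, 0, 1) - .shift(image, 0, -1)) / 2
    gy <- (.shift(image, 1, 0) - .shift(image, -1, 0)) / 2
    # one-sided at the borders
    if (W >= 2) {
      gx[, 1] <- image[, 2] - image[, 1]
      gx[, W] <- image[, W] - image[, W - 1]
    }
    if (H >= 2) {
      gy[1, ] <- image[2, ] - image[1, ]
      gy[H, ] <- image[H, ] - image[H - 1, ]
    }
  } else {
    pad <- rbind(image[1, , drop = FALSE], image, image[H, , drop = FALSE])
    pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, W + 2, drop = FALSE])
    kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8
    gx <- .conv2same(pad, kx[, 3:1])[1 + seq_len(H), 1 + seq_len(W)]
    gy <- .conv2same(pad, t(kx)[3:1, ])[1 + seq_len(H), 1 + seq_len(W)]
  }
  list(gx = gx, gy = gy)
}

#' Gradient angle field
#'
#' Full-quadrant gradient direction \code{atan2(gy, gx)} mapped into
#' [0, 2pi); the 12-bin histogram spans all 360 degrees, so the
#' half-quadrant arctangent of gy/gx alone would alias opposite directions.
#' Pixels with a zero gradient vector have no direction and are returned as
#' \code{NA}.
#'
#' @param g gradient list from \code{\link{computeGradients}}.
#' @return numeric matrix of angles in [0, 2pi), NA where gx = gy = 0.
#' @export
gradientAngle <- function(g) {
  a <- atan2(g$gy, g$gx) %% (2 * pi)
  a[g$gx == 0 & g$gy == 0] <- NA_real_
  a
}

# raster-order window offsets for side w: dy varies slowest
.windowOffsets <- function(window) {
  r <- (window - 1L) %/% 2L
  list(dy = rep(-r:r, each = window), dx = rep(-r:r, times = window), r = r)
}

# colour distance to a reference pixel value; Euclidean over channels for
# colour images, absolute difference for grayscale
.colorDistPatch <- function(patch, center) {
  if (is.matrix(patch)) return(abs(patch - center))
  sqrt(apply(sweep(patch, 3, center)^2, c(1, 2), sum))
}

#' Adaptive window mask around one pixel
#'
#' The descriptor window adapted to its centre: a window pixel is kept only
#' if both its colour distance and its gradient-amplitude difference to the
#' centre pixel stay within the configured thresholds; the centre itself is
#' always kept. Masks are computed on the base image and travel with the
#' base pixel: the same mask is applied to the matching-image window at
#' every candidate disparity.
#'
#' @param image H x W matrix (or H x W x 3 array, colour distance then
#'   Euclidean over channels).
#' @param gradAmp H x W gradient amplitude matrix of the same image.
#' @param center integer c(y, x), at least floor(window/2) from every
#'   border.
#' @param cfg a \code{\link{hogWindowConfig}}.
#' @return logical vector of length window^2 in raster order (dy slowest).
#' @export
adaptiveWindowMask <- function(image, gradAmp, center, cfg = hogWindowConfig()) {
  off <- .windowOffsets(cfg$window)
  y <- center[1] + off$dy; x <- center[2] + off$dx
  gray <- .luma(image)
  H <- nrow(gray); W <- ncol(gray)
  if (any(y < 1 | y > H | x < 1 | x > W))
    stop("window exceeds the image; centre too close to the border")
  if (is.matrix(image)) {
    cd <- abs(gray[cbind(y, x)] - gray[center[1], center[2]])
  } else {
    idx <- cbind(y, x)
    cd <- sqrt((image[cbind(idx, 1)] - image[center[1], center[2], 1])^2 +
               (image[cbind(idx, 2)] - image[center[1], center[2], 2])^2 +
               (image[cbind(idx, 3)] - image[center[1], center[2], 3])^2)
  }
  gd <- abs(gradAmp[cbind(y, x)] - gradAmp[center[1], center[2]])
  mask <- cd <= cfg$rgbThresh & gd <= cfg$gradThresh
  mask[(length(mask) + 1L) %/% 2L] <- TRUE
  mask
}

#' HOG angle descriptor of one window
#'
#' Counts the gradient directions of the in-mask window pixels into
#' \code{nBins} equal half-open bins [k, k+1) * 2pi/nBins and normalizes the
#' histogram to unit sum. Vectors are counted, not magnitude-weighted.
#' Zero-gradient (direction-less) pixels and masked-out pixels do not
#' contribute; if nothing contributes the all-zero vector is returned.
#'
#' @param angles numeric vector/matrix of window angles in [0, 2pi), NA for
#'   undefined.
#' @param gradValid logical, same length: FALSE where the gradient is zero.
#' @param mask logical window mask (all-TRUE for a fixed window).
#' @param cfg a \code{\link{hogWindowConfig}}.
#' @return numeric nBins vector summing to 1 (or all zero).
#' @export
hogAngleDescriptor <- function(angles, gradValid, mask, cfg = hogWindowConfig()) {
  a <- as.vector(angles)
  keep <- as.vector(mask) & as.vector(gradValid) & !is.na(a)
  h <- numeric(cfg$nBins)
  if (any(keep)) {
    bin <- pmin(floor(a[keep] / (2 * pi / cfg$nBins)), cfg$nBins - 1) + 1
    for (b in bin) h[b] <- h[b] + 1
    h <- h / sum(h)
  }
  h
}

#' Relative HOG amplitude descriptor of one window
#'
#' The gradient amplitude of every window pixel divided by the amplitude at
#' the window centre, laid out either positionally (window^2 entries in
#' raster order; masked-out positions contribute 0) or accumulated into the
#' angle bins, then L1-normalized. If the centre amplitude is below
#' \code{1e-6} the ratio is undefined: the descriptor is all-zero and the
#' caller treats the pixel's amplitude cost as the neutral value 1.
#'
#' @param g gradient list from \code{\link{computeGradients}}.
#' @param center integer c(y, x) window centre.
#' @param mask logical window mask in raster order.
#' @param cfg a \code{\link{hogWindowConfig}}.
#' @return numeric vector (length window^2 or nBins), L1 norm 1 or all zero.
#' @export
hogAmplitudeDescriptor <- function(g, center, mask, cfg = hogWindowConfig()) {
  off <- .windowOffsets(cfg$window)
  y <- center[1] + off$dy; x <- center[2] + off$dx
  amp <- sqrt(g$gx^2 + g$gy^2)
  a0 <- amp[center[1], center[2]]
  L <- if (cfg$amplitudeLayout == "positional") cfg$window^2 else cfg$nBins
  v <- numeric(L)
  if (a0 < .EPS_AMP) return(v)
  rho <- amp[cbind(y, x)] / a0
  rho[!mask] <- 0
  if (cfg$amplitudeLayout == "positional") {
    v <- rho
  } else {
    ang <- gradientAngle(g)[cbind(y, x)]
    ok <- mask & !is.na(ang) & rho > 0
    bin <- pmin(floor(ang[ok] / (2 * pi / cfg$nBins)), cfg$nBins - 1) + 1
    for (i in seq_along(bin)) v[bin[i]] <- v[bin[i]] + rho[ok][i]
  }
  s <- sum(v)
  if (s > 0) v / s else numeric(L)
}

# ---- dense field computation -------------------------------------------

# Per-offset adaptive masks for a whole image: logical H x W x window^2,
# mask[, , l] says whether window offset l is kept for each centre pixel.
.adaptiveMasks <- function(image, gradAmp, cfg) {
  gray <- .luma(image)
  H <- nrow(gray); W <- ncol(gray)
  off <- .windowOffsets(cfg$window)
  L <- cfg$window^2
  masks <- array(FALSE, c(H, W, L))
  colorOK <- function(l) {
    if (is.matrix(image)) {
      abs(.shift(gray, off$dy[l], off$dx[l], fill = Inf) - gray) <=
        cfg$rgbThresh
    } else {
      d2 <- (.shift(image[, , 1], off$dy[l], off$dx[l], fill = Inf) -
               image[, , 1])^2 +
            (.shift(image[, , 2], off$dy[l], off$dx[l], fill = 0) -
               image[, , 2])^2 +
            (.shift(image[, , 3], off$dy[l], off$dx[l], fill = 0) -
               image[, , 3])^2
      sqrt(d2) <= cfg$rgbThresh
    }
  }
  for (l in seq_len(L)) {
    if (off$dy[l] == 0L && off$dx[l] == 0L) {
      masks[, , l] <- TRUE
    } else {
      gd <- abs(.shift(gradAmp, off$dy[l], off$dx[l], fill = Inf) - gradAmp)
      masks[, , l] <- colorOK(l) & gd <= cfg$gradThresh
    }
  }
  masks
}

# Dense descriptor computation shared by the fixed and adaptive paths.
# `masks` is NULL (all-true windows) or an H x W x L logical array; `dxShift`
# offsets every window lookup horizontally (used to evaluate matching-image
# descriptors under a base-pixel mask at disparity d: lookups at x - d + dx).
.denseDescriptors <- function(gray, cfg, masks = NULL, dxShift = 0L) {
  H <- nrow(gray); W <- ncol(gray)
  off <- .windowOffsets(cfg$window)
  nb <- cfg$nBins
  g <- computeGradients(gray, cfg$gradientOperator)
  amp <- sqrt(g$gx^2 + g$gy^2)
  ang <- atan2(g$gy, g$gx) %% (2 * pi)
  gradValid <- amp > 0
  bin <- pmin(floor(ang / (2 * pi / nb)), nb - 1) + 1
  binInd <- lapply(seq_len(nb), function(b) (bin == b) & gradValid)

  hist <- array(0, c(H, W, nb))
  positional <- cfg$amplitudeLayout == "positional"
  L <- if (positional) cfg$window^2 else nb
  av <- array(0, c(H, W, L))
  # window-centre amplitude: at x + dxShift when evaluating matching-image
  # descriptors re-indexed by the base pixel
  ampc <- if (dxShift == 0L) amp else .shift(amp, 0L, dxShift)
  flagged <- ampc < .EPS_AMP
  ampSafe <- ifelse(flagged, 1, ampc)

  for (l in seq_len(cfg$window^2)) {
    dy <- off$dy[l]; dx <- off$dx[l] + dxShift
    m <- if (is.null(masks)) 1 else masks[, , l]
    for (b in seq_len(nb))
      hist[, , b] <- hist[, , b] + m * .shift(binInd[[b]], dy, dx)
    rho <- m * .shift(amp, dy, dx) / ampSafe
    if (positional) {
      av[, , l] <- rho
    } else {
      for (b in seq_len(nb))
        av[, , b] <- av[, , b] + rho * .shift(binInd[[b]], dy, dx)
    }
  }

  hs <- matrix(rowSums(matrix(hist, H * W, nb)), H, W)
  hsSafe <- ifelse(hs > 0, hs, 1)
  for (b in seq_len(nb)) hist[, , b] <- hist[, , b] / hsSafe
  as. <- matrix(rowSums(matrix(av, H * W, L)), H, W)
  asSafe <- ifelse(as. > 0, as., 1)
  for (l in seq_len(L)) {
    av[, , l] <- av[, , l] / asSafe
    av[, , l][flagged] <- 0
  }

  r <- off$r
  valid <- matrix(FALSE, H, W)
  if (H > 2 * r && W > 2 * r)
    valid[(r + 1):(H - r), (r + 1):(W - r)] <- TRUE
  list(angleHist = hist, ampVec = av, validMask = valid,
       ampFlagged = flagged, amp = amp)
}

#' Dense descriptor fields of an image
#'
#' Computes the HOG angle and relative HOG amplitude descriptors at every
#' pixel of a grayscale image. With \code{adaptive = TRUE} the window masks
#' are derived from this image (its colour version may be supplied for the
#' colour threshold) and stored in the result; a base image's masks are
#' reused for the matching image at cost-volume build time, where the mask
#' travels with the base pixel across candidate disparities (see
#' \code{\link{hogCostVolume}}).
#'
#' @param image numeric H x W matrix in [0, 255] (or H x W x 3 array).
#' @param cfg a \code{\link{hogWindowConfig}}.
#' @param adaptive logical, overrides \code{cfg$adaptive} if given.
#' @return A \code{\linkS4class{DescriptorField}}.
#' @examples
#' sc <- makeScene(48, 64, dmax = 8, seed = 1)
#' df <- buildDescriptorFields(baseImage(sc), hogWindowConfig())
#' df
#' @export
buildDescriptorFields <- function(image, cfg = hogWindowConfig(),
                                  adaptive = cfg$adaptive) {
  gray <- .luma(image)
  masks <- NULL
  if (isTRUE(adaptive)) {
    g <- computeGradients(gray, cfg$gradientOperator)
    masks <- .adaptiveMasks(image, sqrt(g$gx^2 + g$gy^2), cfg)
  }
  d <- .denseDescriptors(gray, cfg, masks = masks)
  new("DescriptorField", angleHist = d$angleHist, ampVec = d$ampVec,
      validMask = d$validMask, ampFlagged = d$ampFlagged,
      masks = masks, config = cfg)
}
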