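# Vertical-only pyramid and cross-scale cost propagation. Down-sampling
# only the rows lets the fixed-size descriptor window perceive more
# vertical context without shrinking the disparity range, so cost curves at
# all scales share the same length and can be fused directly.

#' Vertical 2:1 down-sampling
#'
#' Averages consecutive row pairs; the width (and with it the disparity
#' range) is unchanged. For odd heights the last row is carried down as is.
#'
#' @param image numeric H x W matrix, H >= 2.
#' @return numeric ceiling(H / 2) x W matrix.
#' @examples
#' downsampleVertical(rbind(c(0, 2), c(2, 4), c(10, 10)))
#' @export
downsampleVertical <- function(image) {
  H <- nrow(image)
  if (H < 2) stop("image must have at least 2 rows")
  odd <- seq(1, H - 1, by = 2)
  out <- (image[odd, , drop = FALSE] + image[odd + 1, , drop = FALSE]) / 2
  if (H %% 2 == 1) out <- rbind(out, image[H, , drop = FALSE])
  out
}

#' Sign-flipped Gaussian kernel
#'
#' A 2-d Gaussian sampled on the integer grid and negated on one half:
#' for the horizontal variant entries with x >= 0 keep the Gaussian value
#' and entries with x < 0 are negated; the vertical variant flips on y
#' instead. Squared responses to these kernels indicate local texture.
#' With \code{zeroCentre = TRUE} the x = 0 column (or y = 0 row) is zeroed,
#' making the kernel exactly antisymmetric: it then has zero net response
#' on constant regions and is insensitive to intensity offsets, which is
#' the form the homogeneity indicator uses.
#'
#' @param cfg a \code{\link{homogeneityConfig}}.
#' @param direction \code{"horizontal"} or \code{"vertical"}.
#' @param zeroCentre logical, zero the flip-axis centre line.
#' @return numeric (2 ky + 1) x (2 kx + 1) matrix, rows indexing y in
#'   [-ky, ky] top to bottom, columns x in [-kx, kx] left to right.
#' @examples
#' k <- flippedGaussianKernel(homogeneityConfig(), "horizontal")
#' @export
flippedGaussianKernel <- function(cfg = homogeneityConfig(),
                                  direction = c("horizontal", "vertical"),
                                  zeroCentre = FALSE) {
  direction <- match.arg(direction)
  kx <- if (is.null(cfg$kernelHalfwidth)) ceiling(3 * cfg$sigmaX)
        else cfg$kernelHalfwidth
  ky <- if (is.null(cfg$kernelHalfwidth)) ceiling(3 * cfg$sigmaY)
        else cfg$kernelHalfwidth
  xs <- -kx:kx; ys <- -ky:ky
  G <- outer(ys, xs, function(y, x)
    exp(-(x^2 / (2 * cfg$sigmaX^2) + y^2 / (2 * cfg$sigmaY^2))) /
      (2 * pi * cfg$sigmaX * cfg$sigmaY))
  if (direction == "horizontal") {
    sgn <- ifelse(xs < 0, -1, 1)
    if (zeroCentre) sgn[xs == 0] <- 0
    G <- sweep(G, 2, sgn, `*`)
  } else {
    sgn <- ifelse(ys < 0, -1, 1)
    if (zeroCentre) sgn[ys == 0] <- 0
    G <- sweep(G, 1, sgn, `*`)
  }
  G
}

#' Texture homogeneity map and simple/complex classification
#'
#' Convolves the image with the horizontal and vertical antisymmetric
#' (zero-centre) sign-flipped Gaussian kernels and takes the sum of the two
#' squared responses as the texture indicator: near zero in homogeneous
#' regions, large around texture and edges. Pixels below the configured
#' quantile of the map are classified simple-texture. The antisymmetric
#' form makes the map zero on constant regions, insensitive to intensity
#' offsets, and scaling as c^2 under gain c — so the quantile-based
#' classification is invariant under the linear radiometric model.
#'
#' @param image numeric H x W grayscale matrix.
#' @param cfg a \code{\link{homogeneityConfig}}.
#' @return list with \code{map} (numeric matrix), \code{simple} (logical
#'   matrix, TRUE = simple texture) and \code{threshold}.
#' @examples
#' sc <- makeScene(48, 64, dmax = 8, layout = "homog-band", seed = 1)
#' h <- homogeneityMap(baseImage(sc), homogeneityConfig())
#' mean(h$simple)
#' @export
homogeneityMap <- function(image, cfg = homogeneityConfig()) {
  if (!is.matrix(image)) stop("image must be a grayscale matrix")
  kH <- flippedGaussianKernel(cfg, "horizontal", zeroCentre = TRUE)
  kV <- flippedGaussianKernel(cfg, "vertical", zeroCentre = TRUE)
  # replicate-pad so truncated border windows keep the antisymmetric
  # cancellation (constant regions respond with exactly zero)
  ky <- (nrow(kH) - 1L) %/% 2L
  kx <- (ncol(kH) - 1L) %/% 2L
  H <- nrow(image); W <- ncol(image)
  pad <- image[c(rep(1L, ky), seq_len(H), rep(H, ky)),
               c(rep(1L, kx), seq_len(W), rep(W, kx)), drop = FALSE]
  crop <- function(M) M[ky + seq_len(H), kx + seq_len(W), drop = FALSE]
  map <- crop(.conv2same(pad, kH))^2 + crop(.conv2same(pad, kV))^2
  thr <- stats::quantile(map, cfg$thresholdQuantile, names = FALSE)
  # <= so that a flat map (constant image) classifies everything simple
  list(map = map, simple = map <= thr, threshold = thr)
}

#' Cross-scale cost volume propagation
#'
#' Fuses per-scale cost volumes from coarsest to finest. At each step every
#' fine row r draws from its nearest-ancestor coarse row floor(r / 2)
#' (0-based; even and odd destination rows share the source), and the fused
#' cost is the pixelwise convex combination
#' \code{w * fine + (1 - w) * coarse} with \code{w = wComplex} where the
#' finer scale classifies the pixel complex-texture and \code{w = wSimple}
#' where simple. Where the coarse entry is invalid the fine value is kept
#' (w = 1). Because every output is a convex combination, cost bounds are
#' preserved, and \code{wSimple = wComplex = 1} reduces to the finest
#' volume. The even/odd fusion leaves mild horizontal stripes in the WTA
#' disparity map; they are inherent to the row-shared propagation and are
#' expected to be removed by any downstream cost-optimization stage.
#'
#' @param volumes list of \code{\linkS4class{CostVolume}}s ordered coarse
#'   to fine; volume s must have ceiling(H / 2) rows of volume s + 1, and
#'   all share W and dmax.
#' @param homogeneity list of logical simple-texture matrices (from
#'   \code{\link{homogeneityMap}}), same order and row counts.
#' @param cfg a \code{\link{propagationConfig}} (its weights are used; the
#'   pyramid depth is \code{length(volumes)}).
#' @return the propagated finest-scale \code{\linkS4class{CostVolume}}.
#' @export
propagateCostVolumes <- function(volumes, homogeneity,
                                 cfg = propagationConfig()) {
  n <- length(volumes)
  if (n == 0) stop("need at least one cost volume")
  if (length(homogeneity) != n)
    stop("need one homogeneity classification per scale")
  prop <- volumes[[1]]
  if (n == 1) return(prop)
  for (s in 2:n) {
    fine <- volumes[[s]]
    Hf <- dim(fine@costs)[1]; W <- dim(fine@costs)[2]
    if (dim(prop@costs)[1] != ceiling(Hf / 2) ||
        dim(prop@costs)[2] != W || prop@dmax != fine@dmax)
      stop("inconsistent pyramid shapes")
    simple <- homogeneity[[s]]
    if (!all(dim(simple) == c(Hf, W)))
      stop("homogeneity classification shape mismatch")
    w <- ifelse(simple, cfg$wSimple, cfg$wComplex)
    src <- (seq_len(Hf) - 1L) %/% 2L + 1L
    out <- fine@costs
    for (d in seq_len(dim(out)[3])) {
      coarse <- prop@costs[src, , d, drop = FALSE][, , 1]
      cvalid <- prop@valid[src, , d, drop = FALSE][, , 1]
      we <- ifelse(cvalid, w, 1)
      out[, , d] <- we * fine@costs[, , d] + (1 - we) * coarse
    }
    prop <- new("CostVolume", costs = out, valid = fine@valid,
                dmax = fine@dmax)
  }
  prop
}
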