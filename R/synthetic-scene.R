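# Synthetic stereo scenes with exact ground truth. Scenes are fronto-
# parallel layered planes; the matching (right) image is produced by
# forward-warping the base image with the ground-truth disparity, applying
# the linear radiometric model g' = c*g + t, and resolving occlusion by
# nearest-surface (largest disparity) wins.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Linear radiometric distortion model
#'
#' The intensity relation between the two views of a stereo pair under
#' restricted lighting: \code{matching = c * base + t}, optionally with
#' additive Gaussian noise. With \code{c = 1, t = 0, noiseSigma = 0} the
#' transform is the identity.
#'
#' @param c multiplicative gain, > 0 (dimensionless).
#' @param t additive offset (intensity units).
#' @param noiseSigma standard deviation of additive Gaussian noise
#'   (intensity units, >= 0).
#' @return A validated named list.
#' @examples
#' radiometricModel(c = 1.5, t = 20)
#' @export
radiometricModel <- function(c = 1, t = 0, noiseSigma = 0) {
  if (c <= 0) stop("gain c must be positive")
  if (noiseSigma < 0) stop("noiseSigma must be non-negative")
  list(c = c, t = t, noiseSigma = noiseSigma)
}

# Visibility under forward warping: base pixel x in a row maps to column
# x - d in the matching image; among sources colliding on one target the
# largest disparity (nearest surface) wins, and out-of-bounds targets are
# occluded.
.visibilityRow <- function(d) {
  x <- seq_along(d)
  t <- x - d
  ord <- order(-d, x)
  win <- !duplicated(t[ord])
  vis <- logical(length(d))
  vis[ord] <- win
  vis & t >= 1
}

.seededTexture <- function(H, W, lo, hi) {
  .boxMean(matrix(stats::runif(H * W, lo, hi), H, W), 1L)
}

#' Generate a synthetic stereo scene
#'
#' Builds a base image and a piecewise-constant ground-truth disparity field
#' for one of several fronto-parallel layouts, together with the occlusion
#' mask implied by forward warping and labels for textured versus
#' homogeneous regions. Deterministic for a fixed seed.
#'
#' Layouts:
#' \describe{
#'   \item{\code{"single-plane"}}{one plane at disparity \code{d}
#'     (default 0), fully textured.}
#'   \item{\code{"two-plane"}}{a textured foreground rectangle at
#'     \code{dFore} over a textured background at \code{dBack}; the
#'     occlusion band of width \code{dFore - dBack} appears left of the
#'     rectangle.}
#'   \item{\code{"homog-band"}}{as \code{"two-plane"} plus a small
#'     full-width homogeneous (constant intensity) horizontal band of height
#'     \code{bandHeight} in the background above the rectangle — the
#'     low-texture failure case the cross-scale propagation targets.}
#'   \item{\code{"thin-bar"}}{a narrow bright vertical bar at \code{dFore}
#'     over a weakly textured background at \code{dBack} — the
#'     high-gradient-outlier case the adaptive window targets.}
#' }
#'
#' @param height,width image size in pixels, each >= 32.
#' @param dmax maximum disparity, 1 <= dmax < width / 4.
#' @param layout layout name, see Details.
#' @param seed integer RNG seed.
#' @param d disparity of the single plane (single-plane layout).
#' @param dBack,dFore background / foreground plane disparities; defaults
#'   round(dmax / 4) and round(5 dmax / 8).
#' @param bandHeight height in pixels of the homogeneous band (homog-band
#'   layout); default height / 4. Each pipeline scale resolves roughly 6
#'   rows inward from either band edge (descriptor window +/- 2 rows, two
#'   cascaded 5x5 box means of the guided filter +/- 4), so a band of
#'   height B is fully resolved once B / 2^(s-1) <= 12; at the reference
#'   128-row scene the default 32-row band is therefore partly ambiguous at
#'   one and at two scales but resolved by three — the
#'   small-homogeneous-region failure mode the cross-scale propagation is
#'   designed for.
#' @param textureRange length-2 intensity range the texture is drawn from
#'   before smoothing. The default [30, 150] leaves headroom so moderate
#'   gain/offset distortions do not clip at 255.
#' @return A \code{\linkS4class{SyntheticScene}}.
#' @examples
#' sc <- makeScene(48, 64, dmax = 8, layout = "two-plane", seed = 3)
#' sc
#' @export
makeScene <- function(height, width, dmax,
                      layout = c("two-plane", "single-plane", "homog-band",
                                 "thin-bar"),
                      seed = 1L, d = 0L, dBack = NULL, dFore = NULL,
                      bandHeight = NULL, textureRange = c(30, 150)) {
  layout <- match.arg(layout)
  height <- as.integer(height); width <- as.integer(width)
  dmax <- as.integer(dmax)
  if (height < 32L || width < 32L) stop("height and width must be >= 32")
  if (dmax < 1L || dmax >= width / 4) stop("need 1 <= dmax < width/4")
  if (is.null(bandHeight)) bandHeight <- as.integer(round(height / 4))
  if (is.null(dBack)) dBack <- max(1L, as.integer(round(dmax / 4)))
  if (is.null(dFore)) dFore <- min(dmax, as.integer(round(5 * dmax / 8)))
  lo <- textureRange[1]; hi <- textureRange[2]
  mid <- (lo + hi) / 2

  gt <- matrix(as.numeric(d), height, width)
  textured <- matrix(TRUE, height, width)

  base <- .withSeed(seed, {
    img <- .seededTexture(height, width, lo, hi)
    if (layout %in% c("two-plane", "homog-band")) {
      gt[, ] <- dBack
      ry <- seq.int(round(height * 0.50), round(height * 0.85))
      rx <- seq.int(round(width * 0.35), round(width * 0.75))
      gt[ry, rx] <- dFore
      if (layout == "homog-band") {
        by <- seq.int(max(2L, round(height * 0.03)),
                      max(2L, round(height * 0.03)) + bandHeight - 1L)
        if (max(by) >= min(ry)) stop("band overlaps the foreground square")
        img[by, ] <- mid
        textured[by, ] <- FALSE
      }
    } else if (layout == "thin-bar") {
      # weak texture: narrow-range noise, unsmoothed, plus a bright bar
      img <- matrix(stats::runif(height * width, mid - 8, mid + 8),
                    height, width)
      gt[, ] <- dBack
      bx <- round(width * 0.6) + 0:2
      img[, bx] <- 235
      gt[, bx] <- dFore
    }
    img
  })
  if (any(gt > dmax)) stop("layout disparities exceed dmax")

  vis <- matrix(FALSE, height, width)
  for (y in seq_len(height)) vis[y, ] <- .visibilityRow(gt[y, ])

  new("SyntheticScene", baseImage = base, gtDisparity = gt,
      occlusionMask = vis, textureMask = textured, dmax = dmax)
}

#' Render the matching image of a synthetic scene
#'
#' Forward-warps the base image with the ground-truth disparity (base pixel
#' \eqn{(x, y)} lands at \eqn{(x - d, y)} in the matching view), applies the
#' linear radiometric model \code{c * g + t}, resolves collisions by largest
#' disparity, fills disoccluded pixels by replicating the nearest filled
#' pixel in the same row (background extension), adds Gaussian noise, and
#' clips to [0, 255]. Intensities stay floating point; quantization only
#' happens if images are written to 8-bit files.
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @param model a \code{\link{radiometricModel}}.
#' @param seed integer seed for the noise draw.
#' @return A \code{\linkS4class{StereoPair}}.
#' @examples
#' sc <- makeScene(48, 64, dmax = 8, seed = 3)
#' pr <- renderMatchingImage(sc, radiometricModel(c = 1.5, t = 20), seed = 4)
#' pr
#' @export
renderMatchingImage <- function(scene, model = radiometricModel(),
                                seed = 1L) {
  base <- scene@baseImage
  gt <- scene@gtDisparity
  H <- nrow(base); W <- ncol(base)
  match <- matrix(NA_real_, H, W)
  for (y in seq_len(H)) {
    d <- gt[y, ]
    x <- seq_len(W)
    t <- x - d
    ord <- order(-d, x)
    win <- ord[!duplicated(t[ord]) & t[ord] >= 1]
    match[y, t[win]] <- model$c * base[y, win] + model$t
    row <- match[y, ]
    filled <- which(!is.na(row))
    if (length(filled) && length(filled) < W) {
      # nearest filled pixel in the row, preferring the left neighbour
      idx <- findInterval(x, filled)
      left <- filled[pmax(idx, 1L)]
      right <- filled[pmin(idx + 1L, length(filled))]
      nearest <- ifelse(idx >= 1L, left, right)
      match[y, ] <- row[nearest]
    } else if (!length(filled)) {
      match[y, ] <- model$c * base[y, ] + model$t
    }
  }
  if (model$noiseSigma > 0)
    match <- match + .withSeed(seed,
      matrix(stats::rnorm(H * W, 0, model$noiseSigma), H, W))
  new("StereoPair", base = base, matching = .clip(match))
}
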