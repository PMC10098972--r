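#' HOG descriptor window configuration
#'
#' Settings for the histogram-of-gradients descriptors: the square window
#' side, the number of angle bins spanning 360 degrees, the adaptive-window
#' thresholds, the amplitude-descriptor layout and the gradient operator.
#'
#' The default 5x5 window and 12 angle bins are the settings under which the
#' method's local linear model is intended to hold; the colour and gradient
#' thresholds gate the adaptive window that excludes outlier pixels (for
#' example a high-contrast foreground structure crossing a background
#' window). The thresholds are tuning parameters with no canonical value;
#' 30 intensity units is a moderate default on 8-bit imagery.
#'
#' @param window odd integer >= 3, window side length in pixels.
#' @param nBins integer >= 4, number of angle bins over [0, 2pi).
#' @param rgbThresh positive colour-distance threshold (intensity units) for
#'   the adaptive window.
#' @param gradThresh positive gradient-amplitude-difference threshold
#'   (intensity/pixel) for the adaptive window.
#' @param adaptive logical; use per-pixel adaptive windows computed on the
#'   base image and carried to the matching image.
#' @param gradientOperator \code{"central"} (central differences, default;
#'   preserves the exact linearity used by the invariance argument) or
#'   \code{"sobel"}.
#' @param amplitudeLayout \code{"positional"} (default): the relative
#'   amplitudes of all window pixels concatenated in raster order, length
#'   window^2. \code{"angular"}: relative amplitudes accumulated into the
#'   nBins angle bins instead.
#' @return A validated named list.
#' @examples
#' cfg <- hogWindowConfig()
#' cfg$window
#' @export
hogWindowConfig <- function(window = 5L, nBins = 12L, rgbThresh = 30,
                            gradThresh = 30, adaptive = FALSE,
                            gradientOperator = c("central", "sobel"),
                            amplitudeLayout = c("positional", "angular")) {
  window <- as.integer(window); nBins <- as.integer(nBins)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  if (nBins < 4L) stop("nBins must be >= 4")
  if (rgbThresh <= 0 || gradThresh <= 0) stop("thresholds must be positive")
  list(window = window, nBins = nBins, rgbThresh = rgbThresh,
       gradThresh = gradThresh, adaptive = isTRUE(adaptive),
       gradientOperator = match.arg(gradientOperator),
       amplitudeLayout = match.arg(amplitudeLayout))
}

#' Guided filter configuration
#'
#' @param radius integer >= 1, window half-width; the default 2 gives the
#'   5x5 filter window matching the descriptor window, keeping one local
#'   linear model size throughout.
#' @param eps positive regularization, in squared units of the [0, 1]
#'   normalized guide.
#' @return A validated named list.
#' @export
guidedFilterConfig <- function(radius = 2L, eps = 1e-4) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1")
  if (eps <= 0) stop("eps must be positive")
  list(radius = radius, eps = eps)
}

#' Texture homogeneity configuration
#'
#' Parameters of the sign-flipped Gaussian kernels whose squared responses
#' indicate local texture, and of the simple/complex split.
#'
#' @param sigmaX,sigmaY positive Gaussian widths in pixels (defaults 2.5 and
#'   1.5, horizontal and vertical).
#' @param kernelHalfwidth integer support half-size per direction, or NULL
#'   for ceiling(3 sigma).
#' @param thresholdQuantile quantile of the homogeneity map in (0, 1) below
#'   which a pixel is classified simple-texture (default median).
#' @return A validated named list.
#' @export
homogeneityConfig <- function(sigmaX = 2.5, sigmaY = 1.5,
                              kernelHalfwidth = NULL,
                              thresholdQuantile = 0.5) {
  if (sigmaX <= 0 || sigmaY <= 0) stop("sigmas must be positive")
  if (thresholdQuantile <= 0 || thresholdQuantile >= 1)
    stop("thresholdQuantile must be in (0, 1)")
  if (!is.null(kernelHalfwidth)) kernelHalfwidth <- as.integer(kernelHalfwidth)
  list(sigmaX = sigmaX, sigmaY = sigmaY, kernelHalfwidth = kernelHalfwidth,
       thresholdQuantile = thresholdQuantile)
}

#' Cross-scale propagation configuration
#'
#' @param nScales integer >= 1 pyramid depth (vertical-only halving).
#' @param wSimple finer-scale fusion weight in (0, 1] used in simple-texture
#'   areas (default 0.3: lean on the coarser, texture-enriched scale).
#' @param wComplex finer-scale weight in complex-texture areas (default 0.7:
#'   trust the detail of the finer scale).
#' @return A validated named list.
#' @export
propagationConfig <- function(nScales = 3L, wSimple = 0.3, wComplex = 0.7) {
  nScales <- as.integer(nScales)
  if (nScales < 1L) stop("nScales must be >= 1")
  if (wSimple <= 0 || wSimple > 1 || wComplex <= 0 || wComplex > 1)
    stop("weights must lie in (0, 1]")
  list(nScales = nScales, wSimple = wSimple, wComplex = wComplex)
}

#' Full pipeline configuration
#'
#' Bundles all stage configurations with the pipeline-level switches. The
#' defaults reproduce the method's reference settings: 5x5 descriptor and
#' filter windows, 12 angle bins, 1:1 fusion of the angle and amplitude cost
#' volumes, guided-filter denoising, three propagation scales with weights
#' 0.3 (simple texture) and 0.7 (complex texture), and Gaussian homogeneity
#' kernels with sigmaX = 2.5, sigmaY = 1.5.
#'
#' @param dmax integer >= 1, maximum disparity searched.
#' @param hog a \code{\link{hogWindowConfig}}.
#' @param guided a \code{\link{guidedFilterConfig}}.
#' @param homogeneity a \code{\link{homogeneityConfig}}.
#' @param propagation a \code{\link{propagationConfig}}.
#' @param fusionRatio weight w in C = w C_angle + (1 - w) C_amplitude;
#'   0.5 is the 1:1 fusion.
#' @param metric \code{"fused"}, \code{"angle"} or \code{"amplitude"}: which
#'   cost volume drives matching.
#' @param filterCosts logical, apply the slice-wise guided filter.
#' @param guide \code{"base"} or \code{"matching"}: which grayscale image
#'   guides the filter (slices are spatially aligned with the base image,
#'   hence the base default).
#' @param lrcTol left-right consistency tolerance in pixels (default 1).
#' @return A validated nested list.
#' @examples
#' cfg <- stereoConfig(dmax = 16)
#' cfg$propagation$nScales
#' @export
stereoConfig <- function(dmax, hog = hogWindowConfig(),
                         guided = guidedFilterConfig(),
                         homogeneity = homogeneityConfig(),
                         propagation = propagationConfig(),
                         fusionRatio = 0.5,
                         metric = c("fused", "angle", "amplitude"),
                         filterCosts = TRUE, guide = c("base", "matching"),
                         lrcTol = 1) {
  dmax <- as.integer(dmax)
  if (dmax < 1L) stop("dmax must be >= 1")
  if (fusionRatio <= 0 || fusionRatio >= 1)
    stop("fusionRatio must be in (0, 1)")
  if (lrcTol < 0) stop("lrcTol must be non-negative")
  list(dmax = dmax, hog = hog, guided = guided, homogeneity = homogeneity,
       propagation = propagation, fusionRatio = fusionRatio,
       metric = match.arg(metric), filterCosts = isTRUE(filterCosts),
       guide = match.arg(guide), lrcTol = lrcTol)
}
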