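# Full matching pipeline: per-scale descriptor costs -> guided filtering
# -> cross-scale propagation -> WTA, run for both views, LRC-checked and
# optionally scored against ground truth.

.flipImage <- function(img) {
  if (is.null(img)) return(NULL)
  if (is.matrix(img)) return(.fliplr(img))
  out <- img
  for (k in seq_len(dim(img)[3])) out[, , k] <- .fliplr(img[, , k])
  out
}

.downsampleImage <- function(img) {
  if (is.null(img)) return(NULL)
  if (is.matrix(img)) return(downsampleVertical(img))
  H2 <- ceiling(dim(img)[1] / 2)
  out <- array(0, c(H2, dim(img)[2], dim(img)[3]))
  for (k in seq_len(dim(img)[3]))
    out[, , k] <- downsampleVertical(img[, , k])
  out
}

#' Single-view disparity through the full cost pipeline
#'
#' Runs the complete cost-volume generation for one view of a rectified
#' pair — per-scale HOG cost volumes (vertical-only pyramid), slice-wise
#' guided filtering, homogeneity-weighted cross-scale propagation — and
#' extracts the WTA disparity. \code{side = "right"} computes the
#' right-image disparity by mirroring both images, running the identical
#' left pipeline, and mirroring the result back (the standard construction
#' for the LRC check).
#'
#' @param pair a \code{\linkS4class{StereoPair}}.
#' @param config a \code{\link{stereoConfig}}.
#' @param side \code{"left"} or \code{"right"}.
#' @return A \code{\linkS4class{DisparityMap}} (WTA validity only; apply
#'   \code{\link{lrcCheck}} for consistency filtering).
#' @export
computeDisparity <- function(pair, config, side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "right") {
    flipped <- new("StereoPair",
                   base = .fliplr(pair@matching), matching = .fliplr(pair@base),
                   baseColor = .flipImage(pair@matchingColor),
                   matchingColor = .flipImage(pair@baseColor))
    dm <- computeDisparity(flipped, config, side = "left")
    return(new("DisparityMap", disparity = .fliplr(dm@disparity),
               valid = .fliplr(dm@valid), dmax = dm@dmax))
  }
  if (config$dmax >= ncol(pair@base))
    stop("dmax must be smaller than the image width")
  nS <- config$propagation$nScales
  volumes <- vector("list", nS)
  simples <- vector("list", nS)
  p <- pair
  for (s in seq_len(nS)) {
    cv <- hogCostVolume(p, config$dmax, config$hog,
                        fusionRatio = config$fusionRatio,
                        metric = config$metric,
                        adaptive = config$hog$adaptive)
    guide <- if (config$guide == "base") p@base else p@matching
    if (config$filterCosts)
      cv <- filterCostVolume(cv, guide, config$guided)
    volumes[[s]] <- cv
    simples[[s]] <- homogeneityMap(p@base, config$homogeneity)$simple
    if (s < nS)
      p <- new("StereoPair",
               base = downsampleVertical(p@base),
               matching = downsampleVertical(p@matching),
               baseColor = .downsampleImage(p@baseColor),
               matchingColor = .downsampleImage(p@matchingColor))
  }
  final <- propagateCostVolumes(rev(volumes), rev(simples),
                                config$propagation)
  wta(final)
}

#' Run the full stereo pipeline on a pair
#'
#' Computes the left and right disparities through the complete pipeline,
#' applies the left-right consistency check, and, when ground truth is
#' supplied, scores the result with the Middlebury-style metrics.
#' Deterministic: the pipeline itself draws no random numbers.
#'
#' @param pair a \code{\linkS4class{StereoPair}}.
#' @param config a \code{\link{stereoConfig}}.
#' @param gt optional ground-truth disparity matrix.
#' @param evalMask optional logical matrix of assessed pixels (e.g. the
#'   non-occluded mask of a \code{\linkS4class{SyntheticScene}}).
#' @param allPixels passed to \code{\link{evaluateDisparity}}.
#' @return list with \code{disparity} (LRC-checked
#'   \code{\linkS4class{DisparityMap}}), \code{left}, \code{right} (raw WTA
#'   maps) and \code{report} (a \code{\linkS4class{QualityReport}} or NULL).
#' @examples
#' sc <- makeScene(48, 64, dmax = 6, seed = 5)
#' pr <- renderMatchingImage(sc)
#' res <- runPipeline(pr, stereoConfig(dmax = 6,
#'   propagation = propagationConfig(nScales = 1)),
#'   gt = gtDisparity(sc), evalMask = occlusionMask(sc))
#' res$report
#' @export
runPipeline <- function(pair, config, gt = NULL, evalMask = NULL,
                        allPixels = FALSE) {
  dL <- computeDisparity(pair, config, side = "left")
  dR <- computeDisparity(pair, config, side = "right")
  dm <- lrcCheck(dL, dR, tol = config$lrcTol)
  report <- NULL
  if (!is.null(gt))
    report <- evaluateDisparity(dm, gt, evalMask, allPixels = allPixels)
  list(disparity = dm, left = dL, right = dR, report = report)
}

#' Ablation sweep over one pipeline axis
#'
#' Re-runs the pipeline while varying a single design axis and tabulates
#' the quality reports: \code{"metric"} (angle, amplitude, fused),
#' \code{"scales"} (1 .. nScales), \code{"filtering"} (guided filter off /
#' on) or \code{"adaptive"} (fixed / adaptive windows).
#'
#' @param pair a \code{\linkS4class{StereoPair}}.
#' @param config the base \code{\link{stereoConfig}}.
#' @param axis one of \code{"metric"}, \code{"scales"}, \code{"filtering"},
#'   \code{"adaptive"}.
#' @param gt ground-truth disparity matrix (required; the sweep is scored).
#' @param evalMask optional logical matrix of assessed pixels.
#' @return data.frame with one row per level: level, bad1_0, bad2_0,
#'   invalid, totBad, avgErr.
#' @export
runAblation <- function(pair, config,
                        axis = c("metric", "scales", "filtering", "adaptive"),
                        gt, evalMask = NULL) {
  axis <- match.arg(axis)
  configs <- switch(axis,
    metric = {
      lv <- c("angle", "amplitude", "fused")
      stats::setNames(lapply(lv, function(m) { config$metric <- m; config }),
                      lv)
    },
    scales = {
      lv <- seq_len(config$propagation$nScales)
      stats::setNames(lapply(lv, function(s) {
        config$propagation$nScales <- as.integer(s); config
      }), paste0("scales", lv))
    },
    filtering = {
      stats::setNames(lapply(c(FALSE, TRUE), function(f) {
        config$filterCosts <- f; config
      }), c("unfiltered", "filtered"))
    },
    adaptive = {
      stats::setNames(lapply(c(FALSE, TRUE), function(a) {
        config$hog$adaptive <- a; config
      }), c("fixed", "adaptive"))
    })
  rows <- lapply(names(configs), function(nm) {
    rep <- runPipeline(pair, configs[[nm]], gt = gt,
                       evalMask = evalMask)$report
    cbind(data.frame(level = nm, stringsAsFactors = FALSE),
          as.data.frame(as.list(rep)[c("bad1_0", "bad2_0", "invalid",
                                       "totBad", "avgErr")]))
  })
  do.call(rbind, rows)
}
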