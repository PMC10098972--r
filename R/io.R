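# File formats: 8-bit PNG images, Middlebury PFM float maps (the V3
# dialect: little-endian, scale header -1.0, rows bottom to top), JSON
# quality reports and a flat-binary cost-volume dump with a JSON sidecar.

#' Read / write Middlebury PFM disparity maps
#'
#' Grayscale portable float maps as used for Middlebury ground-truth
#' disparities: header lines \code{Pf}, \code{width height}, and the scale
#' whose sign encodes endianness (written as -1.0, little-endian), followed
#' by raw 32-bit floats in rows ordered bottom to top.
#'
#' @param path file path.
#' @return \code{readPFM}: a numeric H x W matrix.
#' @export
readPFM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!identical(magic, "Pf")) stop("not a grayscale PFM file")
  dims <- scan(text = readLines(con, 1), what = integer(), quiet = TRUE)
  sc <- scan(text = readLines(con, 1), what = numeric(), quiet = TRUE)
  W <- dims[1]; H <- dims[2]
  v <- readBin(con, "numeric", n = W * H, size = 4,
               endian = if (sc < 0) "little" else "big")
  # rows are stored bottom-to-top
  m <- matrix(v, H, W, byrow = TRUE)
  m[rev(seq_len(H)), , drop = FALSE]
}

#' @rdname readPFM
#' @param disparity numeric H x W matrix to write.
#' @return \code{writePFM}: the path, invisibly.
#' @export
writePFM <- function(disparity, path) {
  H <- nrow(disparity); W <- ncol(disparity)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("Pf", sprintf("%d %d", W, H), "-1.0"), con, sep = "\n")
  v <- as.vector(t(disparity[rev(seq_len(H)), , drop = FALSE]))
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' Read / write 8-bit images
#'
#' Thin wrappers around the png package using this package's intensity
#' convention ([0, 255], matrix rows = image rows). Colour PNGs are
#' returned as H x W x 3 arrays.
#'
#' @param path file path.
#' @return \code{readImagePNG}: matrix or H x W x 3 array in [0, 255].
#' @export
readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L)
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img * 255
}

#' @rdname readImagePNG
#' @param image matrix or H x W x 3 array in [0, 255].
#' @return \code{writeImagePNG}: the path, invisibly.
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(.clip(image) / 255, path)
  invisible(path)
}

#' Read a rectified stereo pair from image files
#'
#' Colour images are converted to ITU-R 601 luma for matching; the colour
#' planes are retained for the adaptive-window colour threshold.
#'
#' @param basePath,matchingPath PNG file paths (left and right image).
#' @return A \code{\linkS4class{StereoPair}}.
#' @export
readStereoPair <- function(basePath, matchingPath) {
  b <- readImagePNG(basePath); m <- readImagePNG(matchingPath)
  new("StereoPair", base = .luma(b), matching = .luma(m),
      baseColor = if (is.matrix(b)) NULL else b,
      matchingColor = if (is.matrix(m)) NULL else m)
}

#' Render a disparity map with LRC failures as white pixels
#'
#' Writes a PNG visualization: valid disparities scaled to [0, dmax] gray
#' levels, pixels failing the validity/LRC check in white.
#'
#' @param d a \code{\linkS4class{DisparityMap}}.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeDisparityPNG <- function(d, path) {
  img <- d@disparity / max(d@dmax, 1) * 220
  img[!d@valid] <- 255
  writeImagePNG(img, path)
}

#' Write a quality report as JSON
#'
#' @param report a \code{\linkS4class{QualityReport}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Dump / load a cost volume as flat binary + JSON sidecar
#'
#' The costs are written as little-endian 32-bit floats in R array order
#' (y fastest, then x, then disparity), the validity mask as raw bytes,
#' and \code{<path>.json} records the shape and dmax, so external cost
#' optimizers can consume the volume.
#'
#' @param cv a \code{\linkS4class{CostVolume}}.
#' @param path output path for the binary payload.
#' @return \code{dumpCostVolume}: the path invisibly;
#'   \code{loadCostVolume}: the \code{\linkS4class{CostVolume}}.
#' @export
dumpCostVolume <- function(cv, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(cv@costs), con, size = 4, endian = "little")
  writeBin(as.raw(cv@valid), con)
  jsonlite::write_json(
    list(shape = dim(cv@costs), dmax = cv@dmax, dtype = "float32le"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname dumpCostVolume
#' @export
loadCostVolume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  costs <- array(readBin(con, "numeric", n, size = 4, endian = "little"),
                 meta$shape)
  valid <- array(as.logical(readBin(con, "raw", n)), meta$shape)
  new("CostVolume", costs = costs, valid = valid,
      dmax = as.integer(meta$dmax))
}
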