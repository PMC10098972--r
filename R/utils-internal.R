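# Internal array helpers shared across modules. Image convention: matrices
# indexed [y, x] with y down the rows and x across the columns.

# out[y, x] = M[y + dy, x + dx], `fill` outside.
.shift <- function(M, dy, dx, fill = 0) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(fill, H, W)
  ys <- seq_len(H) + dy; xs <- seq_len(W) + dx
  yok <- ys >= 1L & ys <= H; xok <- xs >= 1L & xs <= W
  if (any(yok) && any(xok))
    out[yok, xok] <- M[ys[yok], xs[xok], drop = FALSE]
  out
}

# Summed-area table with a leading zero row/column so that window sums
# reduce to four lookups.
.integral <- function(M) {
  ii <- apply(M, 2, cumsum)
  if (is.null(dim(ii))) ii <- matrix(ii, nrow = nrow(M))
  ii <- t(apply(rbind(0, ii), 1, cumsum))
  cbind(0, ii)[, seq_len(ncol(M) + 1L), drop = FALSE]
}

# Sum of M over the (2r+1)^2 window centred at each pixel, windows clipped
# at the image border (shrinking windows).
.boxSum <- function(M, r) {
  H <- nrow(M); W <- ncol(M)
  ii <- .integral(M)
  y1 <- pmax(seq_len(H) - r, 1L); y2 <- pmin(seq_len(H) + r, H)
  x1 <- pmax(seq_len(W) - r, 1L); x2 <- pmin(seq_len(W) + r, W)
  ii[y2 + 1L, x2 + 1L, drop = FALSE] - ii[y1, x2 + 1L, drop = FALSE] -
    ii[y2 + 1L, x1, drop = FALSE] + ii[y1, x1, drop = FALSE]
}

# Number of in-image pixels in each clipped window (denominator for
# shrinking-window means).
.boxCount <- function(H, W, r) {
  ny <- pmin(seq_len(H) + r, H) - pmax(seq_len(H) - r, 1L) + 1L
  nx <- pmin(seq_len(W) + r, W) - pmax(seq_len(W) - r, 1L) + 1L
  outer(ny, nx)
}

.boxMean <- function(M, r) .boxSum(M, r) / .boxCount(nrow(M), ncol(M), r)

# 2-d convolution, 'same' output size, zero padding. K rows index the
# vertical kernel coordinate, columns the horizontal one, centre at the
# middle entry. Accumulates shifted copies; kernels here are small.
.conv2same <- function(M, K) {
  kh <- nrow(K); kw <- ncol(K)
  cy <- (kh + 1L) %/% 2L; cx <- (kw + 1L) %/% 2L
  out <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      k <- K[i, j]
      if (k != 0)
        out <- out + k * .shift(M, cy - i, cx - j)
    }
  }
  out
}

.clip <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# ITU-R 601 luma for H x W x 3 arrays; matrices pass through.
.luma <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L)
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  stop("image must be an H x W matrix or H x W x 3 array")
}

# Horizontal mirror, used to run the right image through the left-image
# pipeline for the LRC check.
.fliplr <- function(M) M[, rev(seq_len(ncol(M))), drop = FALSE]
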