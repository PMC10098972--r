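# Independent brute-force oracles: literal per-pixel loop implementations
# used to pin down the vectorized code. Deliberately slow and simple.

# central differences with one-sided borders, per-pixel loop
oracleGradients <- function(I) {
  H <- nrow(I); W <- ncol(I)
  gx <- gy <- matrix(0, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      gx[y, x] <- if (x == 1) I[y, 2] - I[y, 1]
        else if (x == W) I[y, W] - I[y, W - 1]
        else (I[y, x + 1] - I[y, x - 1]) / 2
      gy[y, x] <- if (y == 1) I[2, x] - I[1, x]
        else if (y == H) I[H, x] - I[H - 1, x]
        else (I[y + 1, x] - I[y - 1, x]) / 2
    }
  }
  list(gx = gx, gy = gy)
}

# literal guided filter: per-window affine fits, then per-pixel average of
# the models of every window containing the pixel
oracleGuidedFilter <- function(p, I, r, eps) {
  H <- nrow(I); W <- ncol(I)
  a <- b <- matrix(0, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      ys <- max(1, y - r):min(H, y + r)
      xs <- max(1, x - r):min(W, x + r)
      Iw <- I[ys, xs]; pw <- p[ys, xs]
      mI <- mean(Iw); mP <- mean(pw)
      vI <- mean(Iw * Iw) - mI^2
      cIP <- mean(Iw * pw) - mI * mP
      a[y, x] <- cIP / (vI + eps)
      b[y, x] <- mP - a[y, x] * mI
    }
  }
  q <- matrix(0, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      ys <- max(1, y - r):min(H, y + r)
      xs <- max(1, x - r):min(W, x + r)
      q[y, x] <- mean(a[ys, xs]) * I[y, x] + mean(b[ys, xs])
    }
  }
  q
}

# forward-warp collision detection: a base pixel is visible iff its warp
# target is in bounds and no other pixel with larger disparity (or equal
# disparity and smaller x) claims the same target
oracleVisibility <- function(gt) {
  H <- nrow(gt); W <- ncol(gt)
  vis <- matrix(FALSE, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      t <- x - gt[y, x]
      if (t < 1) next
      beaten <- FALSE
      for (x2 in seq_len(W)) {
        if (x2 == x || x2 - gt[y, x2] != t) next
        if (gt[y, x2] > gt[y, x] ||
            (gt[y, x2] == gt[y, x] && x2 < x)) beaten <- TRUE
      }
      if (!beaten) vis[y, x] <- TRUE
    }
  }
  vis
}

# loop-and-count angle histogram over a window
oracleAngleHist <- function(angles, gradValid, mask, nBins) {
  h <- numeric(nBins)
  a <- as.vector(angles); v <- as.vector(gradValid); m <- as.vector(mask)
  for (i in seq_along(a)) {
    if (!m[i] || !v[i] || is.na(a[i])) next
    b <- floor(a[i] / (2 * pi / nBins)) + 1
    if (b > nBins) b <- 1
    h[b] <- h[b] + 1
  }
  if (sum(h) > 0) h / sum(h) else h
}

# loop argmin WTA respecting the validity mask, ties to smallest d
oracleWTA <- function(costs, valid) {
  H <- dim(costs)[1]; W <- dim(costs)[2]; D <- dim(costs)[3]
  disp <- matrix(0, H, W); ok <- matrix(FALSE, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      best <- Inf; bd <- 0
      for (d in seq_len(D)) {
        if (valid[y, x, d] && costs[y, x, d] < best) {
          best <- costs[y, x, d]; bd <- d - 1; ok[y, x] <- TRUE
        }
      }
      disp[y, x] <- bd
    }
  }
  list(disparity = disp, valid = ok)
}

# loop-based Middlebury metric counting
oracleEvaluate <- function(disp, valid, gt, evalMask) {
  nEval <- 0; nUse <- 0; nBad1 <- 0; nBad2 <- 0; nInv <- 0; sErr <- 0
  for (i in seq_along(disp)) {
    if (!evalMask[i]) next
    nEval <- nEval + 1
    if (!valid[i]) { nInv <- nInv + 1; next }
    nUse <- nUse + 1
    e <- abs(disp[i] - gt[i])
    sErr <- sErr + e
    if (e > 1) nBad1 <- nBad1 + 1
    if (e > 2) nBad2 <- nBad2 + 1
  }
  list(bad1_0 = 100 * nBad1 / nUse, bad2_0 = 100 * nBad2 / nUse,
       invalid = 100 * nInv / nEval,
       totBad = 100 * nBad1 / nUse + 100 * nInv / nEval,
       avgErr = sErr / nUse)
}

# smooth random test image with intensities in [lo, hi]: blurring keeps
# dense gradients while bounding the range
randomImage <- function(H, W, seed, lo = 40, hi = 100) {
  set.seed(seed)
  m <- matrix(runif(H * W, lo, hi), H, W)
  (m + 0.25 * (rbind(m[-1, ], m[H, ]) + rbind(m[1, ], m[-H, ]))) / 1.5
}
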