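test_that("vertical down-sampling averages row pairs and keeps width", {
  a <- matrix(1, 1, 5); b <- matrix(3, 1, 5)
  img <- rbind(a, a, b, b)
  expect_equal(downsampleVertical(img), rbind(a, b))
  ramp <- outer(seq_len(6), seq_len(8), function(y, x) as.numeric(x))
  expect_equal(downsampleVertical(ramp), ramp[c(1, 3, 5), ])
  set.seed(151)
  I <- matrix(runif(9 * 7), 9, 7)
  out <- downsampleVertical(I)
  expect_equal(dim(out), c(5L, 7L))
  for (r in 1:4) expect_equal(out[r, ], (I[2 * r - 1, ] + I[2 * r, ]) / 2)
  expect_equal(out[5, ], I[9, ])  # odd height: last row carried down
})

test_that("sign-flipped Gaussian kernel follows the definition", {
  cfg <- homogeneityConfig(sigmaX = 2.5, sigmaY = 1.5)
  k <- flippedGaussianKernel(cfg, "horizontal")
  kx <- ceiling(3 * 2.5); ky <- ceiling(3 * 1.5)
  expect_equal(dim(k), c(2 * ky + 1, 2 * kx + 1))
  ix <- function(x) kx + 1 + x; iy <- function(y) ky + 1 + y
  # sign rule: f(-1, 0) = -f(1, 0); x = 0 column kept positive
  expect_equal(k[iy(0), ix(-1)], -k[iy(0), ix(1)])
  expect_gt(k[iy(0), ix(0)], 0)
  # direct evaluation at (x, y) = (2, 1)
  expect_equal(k[iy(1), ix(2)],
               exp(-(4 / 12.5 + 1 / 4.5)) / (2 * pi * 2.5 * 1.5))
  # antisymmetric halves cancel: total mass = mass of the x = 0 column
  expect_equal(sum(k), sum(k[, ix(0)]))
  # vertical variant flips on y instead
  kv <- flippedGaussianKernel(cfg, "vertical")
  expect_equal(kv[iy(-1), ix(2)], -kv[iy(1), ix(2)])
  # zero-centre form is exactly antisymmetric
  kz <- flippedGaussianKernel(cfg, "horizontal", zeroCentre = TRUE)
  expect_equal(sum(kz), 0)
})

test_that("homogeneity map is zero on constants, offset-invariant and edge-peaked", {
  cfg <- homogeneityConfig()
  h <- homogeneityMap(matrix(42, 24, 40), cfg)
  expect_lt(max(abs(h$map)), 1e-18)
  expect_true(all(h$simple))
  # vertical step edge: response peaks in the columns around the edge
  I <- matrix(0, 32, 64); I[, 33:64] <- 100
  h <- homogeneityMap(I, cfg)
  peak <- which(h$map == max(h$map), arr.ind = TRUE)
  expect_true(all(abs(peak[, 2] - 32.5) <= 2))
  # adding an intensity offset leaves the map unchanged
  h2 <- homogeneityMap(I + 57, cfg)
  expect_lt(max(abs(h$map - h2$map)), 1e-9 * max(h$map))
  # direct convolution oracle at one interior pixel
  kH <- flippedGaussianKernel(cfg, "horizontal", zeroCentre = TRUE)
  kV <- flippedGaussianKernel(cfg, "vertical", zeroCentre = TRUE)
  y <- 16; x <- 40
  cH <- 0; cV <- 0
  kx <- (ncol(kH) - 1) / 2; ky <- (nrow(kH) - 1) / 2
  for (dy in -ky:ky) for (dx in -kx:kx) {
    cH <- cH + kH[ky + 1 + dy, kx + 1 + dx] * I[y - dy, x - dx]
    cV <- cV + kV[ky + 1 + dy, kx + 1 + dx] * I[y - dy, x - dx]
  }
  expect_equal(h$map[y, x], cH^2 + cV^2)
})

test_that("cross-scale propagation blends nearest-ancestor rows convexly", {
  mkcv <- function(M, dmax = 2) {
    C <- array(0, c(nrow(M), ncol(M), dmax + 1))
    for (d in seq_len(dmax + 1)) C[, , d] <- M * d
    new("CostVolume", costs = C, valid = array(TRUE, dim(C)),
        dmax = as.integer(dmax))
  }
  cfg <- propagationConfig(nScales = 2, wSimple = 0.3, wComplex = 0.7)
  # single scale: identity
  v <- mkcv(matrix(runif(12), 3, 4))
  expect_identical(propagateCostVolumes(list(v), list(matrix(FALSE, 3, 4))),
                   v)
  # two-row toy, all complex: out r = 0.7 fine_r + 0.3 coarse_floor(r/2)
  f <- matrix(c(2, 6), 2, 1); c0 <- matrix(4, 1, 1)
  out <- propagateCostVolumes(list(mkcv(c0), mkcv(f)),
                              list(matrix(FALSE, 1, 1), matrix(FALSE, 2, 1)),
                              cfg)
  for (d in 1:3) {
    expect_equal(costs(out)[1, 1, d], (0.7 * 2 + 0.3 * 4) * d)
    expect_equal(costs(out)[2, 1, d], (0.7 * 6 + 0.3 * 4) * d)
  }
  # simple-texture weight selected from the finer scale's classification
  out2 <- propagateCostVolumes(list(mkcv(c0), mkcv(f)),
                               list(matrix(FALSE, 1, 1), matrix(TRUE, 2, 1)),
                               cfg)
  expect_equal(costs(out2)[1, 1, 1], 0.3 * 2 + 0.7 * 4)
  # identical constant volumes: any weights return the same volume
  cv1 <- mkcv(matrix(5, 1, 4)); cv2 <- mkcv(matrix(5, 2, 4))
  eq <- propagateCostVolumes(list(cv1, cv2),
                             list(matrix(TRUE, 1, 4),
                                  matrix(c(TRUE, FALSE), 2, 4)), cfg)
  expect_equal(costs(eq), costs(cv2))
  # w = 1 on both labels reduces to the finest volume
  idc <- propagationConfig(nScales = 2, wSimple = 1, wComplex = 1)
  idv <- propagateCostVolumes(list(mkcv(c0), mkcv(f)),
                              list(matrix(FALSE, 1, 1),
                                   matrix(c(TRUE, FALSE), 2, 1)), idc)
  expect_equal(costs(idv), costs(mkcv(f)))
  expect_error(propagateCostVolumes(list(mkcv(f), mkcv(f)),
                                    list(matrix(TRUE, 2, 1),
                                         matrix(TRUE, 2, 1)), cfg),
               "pyramid")
})

test_that("propagated costs stay within the per-scale cost bounds", {
  set.seed(161)
  H <- 8; W <- 6; D <- 4L
  mk <- function(Hs) {
    C <- array(runif(Hs * W * D, 1, 3), c(Hs, W, D))
    new("CostVolume", costs = C, valid = array(TRUE, dim(C)), dmax = D - 1L)
  }
  vols <- list(mk(2), mk(4), mk(8))
  hom <- list(matrix(runif(2 * W) > 0.5, 2, W),
              matrix(runif(4 * W) > 0.5, 4, W),
              matrix(runif(8 * W) > 0.5, 8, W))
  out <- propagateCostVolumes(vols, hom, propagationConfig(nScales = 3))
  lo <- min(vapply(vols, function(v) min(costs(v)), 0))
  hi <- max(vapply(vols, function(v) max(costs(v)), 0))
  expect_true(all(costs(out) >= lo - 1e-12 & costs(out) <= hi + 1e-12))
})
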