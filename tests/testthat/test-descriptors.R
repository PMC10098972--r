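test_that("gradients match ramps, constants and a per-pixel loop oracle", {
  ramp <- outer(seq_len(10), seq_len(12), function(y, x) as.numeric(x))
  g <- computeGradients(ramp)
  expect_true(all(g$gx[, 2:11] == 1))
  expect_true(all(g$gy == 0))
  g0 <- computeGradients(matrix(7, 8, 8))
  expect_true(all(g0$gx == 0) && all(g0$gy == 0))
  I <- randomImage(16, 16, seed = 11)
  g1 <- computeGradients(I)
  o <- oracleGradients(I)
  expect_identical(g1$gx, o$gx)
  expect_identical(g1$gy, o$gy)
  expect_error(computeGradients(array(0, c(4, 4, 3))), "matrix")
})

test_that("gradient angles cover all four quadrants and flag zero vectors", {
  g <- list(gx = matrix(c(1, 0, -1, 0), 2), gy = matrix(c(0, 1, -1, 0), 2))
  a <- gradientAngle(g)
  expect_equal(a[1, 1], 0)
  expect_equal(a[2, 1], pi / 2)
  expect_equal(a[1, 2], 5 * pi / 4)
  expect_true(is.na(a[2, 2]))
})

test_that("adaptive window masks follow both thresholds and a loop oracle", {
  cfg <- hogWindowConfig(rgbThresh = 50, gradThresh = 1e6)
  patch <- matrix(0, 11, 11)
  g <- computeGradients(patch)
  expect_true(all(adaptiveWindowMask(patch, sqrt(g$gx^2 + g$gy^2),
                                     c(6, 6), cfg)))
  patch[4, 6] <- 255  # one bright outlier inside the 5x5 window of (6, 6)
  g <- computeGradients(patch)
  m <- adaptiveWindowMask(patch, abs(g$gx) * 0, c(6, 6), cfg)
  bad <- which(!m)
  # offset (-2, 0) in raster order (dy slowest): index 3
  expect_identical(bad, 3L)
  # random patch, random thresholds, against a literal loop
  set.seed(21)
  img <- matrix(runif(121, 0, 255), 11, 11)
  g <- computeGradients(img)
  amp <- sqrt(g$gx^2 + g$gy^2)
  cfg <- hogWindowConfig(rgbThresh = 40, gradThresh = 15)
  m <- adaptiveWindowMask(img, amp, c(5, 7), cfg)
  i <- 0
  for (dy in -2:2) for (dx in -2:2) {
    i <- i + 1
    expected <- (abs(img[5 + dy, 7 + dx] - img[5, 7]) <= 40 &&
                 abs(amp[5 + dy, 7 + dx] - amp[5, 7]) <= 15) ||
                (dy == 0 && dx == 0)
    expect_identical(m[i], expected)
  }
})

test_that("angle histograms bin, normalize and match the count oracle", {
  cfg <- hogWindowConfig()
  ang <- matrix(pi / 4, 5, 5)          # 45 degrees
  ok <- matrix(TRUE, 5, 5)
  h <- hogAngleDescriptor(ang, ok, ok, cfg)
  expect_equal(h[2], 1)                 # bin [30, 60) degrees
  expect_equal(sum(h), 1)
  one <- (0:11 + 0.5) * pi / 6          # one angle per 30-degree bin
  h <- hogAngleDescriptor(one, rep(TRUE, 12), rep(TRUE, 12), cfg)
  expect_equal(h, rep(1 / 12, 12))
  set.seed(31)
  ang <- matrix(runif(25, 0, 2 * pi), 5, 5)
  gv <- matrix(runif(25) > 0.2, 5, 5)
  mk <- matrix(runif(25) > 0.3, 5, 5)
  expect_equal(hogAngleDescriptor(ang, gv, mk, cfg),
               oracleAngleHist(ang, gv, mk, 12))
})

test_that("amplitude descriptors are centre-relative and L1-normalized", {
  cfg <- hogWindowConfig()
  # uniform gradient field: all relative amplitudes are 1
  I <- outer(seq_len(11), seq_len(11), function(y, x) 2 * x + 3 * y)
  g <- computeGradients(I)
  mask <- rep(TRUE, 25)
  v <- hogAmplitudeDescriptor(g, c(6, 6), mask, cfg)
  expect_equal(v, rep(1 / 25, 25))
  # the centre entry before normalization is 1: centre index carries 1/sum
  set.seed(41)
  I <- matrix(runif(121, 0, 255), 11, 11)
  g <- computeGradients(I)
  v <- hogAmplitudeDescriptor(g, c(6, 6), mask, cfg)
  amp <- sqrt(g$gx^2 + g$gy^2)
  # raster order (dy slowest, dx fastest) = row-major window traversal
  rho <- as.vector(t(amp[4:8, 4:8])) / amp[6, 6]
  expect_equal(v, rho / sum(rho))
  expect_equal(v[13] * sum(rho), 1)  # centre ratio is 1 before normalizing
  # radiometric invariance of the descriptor
  g2 <- computeGradients(1.5 * I + 20)
  v2 <- hogAmplitudeDescriptor(g2, c(6, 6), mask, cfg)
  expect_lt(max(abs(v - v2)), 1e-9)
  # zero-gradient centre: all-zero descriptor
  flat <- matrix(5, 11, 11)
  vz <- hogAmplitudeDescriptor(computeGradients(flat), c(6, 6), mask, cfg)
  expect_true(all(vz == 0))
})

test_that("descriptor fields are invariant, normalized and self-consistent", {
  I <- randomImage(32, 32, seed = 51)
  cfg <- hogWindowConfig()
  df <- buildDescriptorFields(I, cfg)
  # constant image: everything flagged / all-zero
  dfc <- buildDescriptorFields(matrix(9, 32, 32), cfg)
  expect_true(all(angleHist(dfc) == 0) && all(ampVec(dfc) == 0))
  expect_true(all(dfc@ampFlagged))
  # invariance under c = 2, t = -10
  df2 <- buildDescriptorFields(2 * I - 10, cfg)
  expect_lt(max(abs(angleHist(df) - angleHist(df2))), 1e-9)
  expect_lt(max(abs(ampVec(df) - ampVec(df2))), 1e-9)
  # L1 norms in {0, 1}
  hsum <- apply(angleHist(df), c(1, 2), sum)
  asum <- apply(ampVec(df), c(1, 2), sum)
  expect_true(all(abs(hsum) < 1e-12 | abs(hsum - 1) < 1e-12))
  expect_true(all(abs(asum) < 1e-12 | abs(asum - 1) < 1e-12))
  expect_true(all(angleHist(df) >= 0) && all(ampVec(df) >= 0))
  # field values reproduce the standalone per-pixel operations
  g <- computeGradients(I)
  ang <- gradientAngle(g)
  amp <- sqrt(g$gx^2 + g$gy^2)
  for (centre in list(c(5, 7), c(16, 16), c(30, 3))) {
    y <- centre[1]; x <- centre[2]
    win <- function(M) M[(y - 2):(y + 2), (x - 2):(x + 2)]
    # raster order (dy slowest) = row-major traversal of the window
    rast <- function(M) as.vector(t(win(M)))
    expect_equal(angleHist(df)[y, x, ],
                 oracleAngleHist(rast(ang), rast(amp > 0),
                                 rep(TRUE, 25), 12))
    expect_equal(ampVec(df)[y, x, ],
                 hogAmplitudeDescriptor(g, centre, rep(TRUE, 25), cfg))
  }
  # adaptive field equals per-pixel masks + per-pixel descriptors
  cfgA <- hogWindowConfig(rgbThresh = 20, gradThresh = 10, adaptive = TRUE)
  dfa <- buildDescriptorFields(I, cfgA)
  for (centre in list(c(8, 9), c(20, 25))) {
    y <- centre[1]; x <- centre[2]
    m <- adaptiveWindowMask(I, amp, centre, cfgA)
    expect_identical(as.logical(dfa@masks[y, x, ]), as.logical(m))
    win <- function(M) M[(y - 2):(y + 2), (x - 2):(x + 2)]
    rast <- function(M) as.vector(t(win(M)))
    expect_equal(angleHist(dfa)[y, x, ],
                 oracleAngleHist(rast(ang), rast(amp > 0), m, 12))
    expect_equal(ampVec(dfa)[y, x, ],
                 hogAmplitudeDescriptor(g, centre, m, cfgA))
  }
})
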