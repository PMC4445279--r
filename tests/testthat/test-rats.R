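# Robust adaptive threshold selection.

test_that("Sobel gradient matches hand-derived responses", {
  expect_equal(sobelGradient(matrix(5, 8, 8)), matrix(0, 8, 8))

  # vertical 0|10 step on constant rows: response only in the two flanking
  # columns, magnitude |gx| = 40 (hand convolution of the 3x3 kernel)
  sl <- matrix(0, 8, 10); sl[, 6:10] <- 10
  G <- sobelGradient(sl)
  expect_equal(which(colSums(G) > 0), c(5L, 6L))
  expect_true(all(G[, 5] == 40))
  expect_true(all(G[, 6] == 40))

  # linearity in the input scale
  set.seed(1)
  r <- matrix(runif(64), 8, 8)
  expect_equal(sobelGradient(3.5 * r), 3.5 * sobelGradient(r))

  expect_error(sobelGradient(matrix(0, 2, 5)), "3 x 3")
})

test_that("leaflet threshold is the gradient-weighted intensity mean", {
  sl <- matrix(0, 8, 10); sl[, 6:10] <- 10
  G <- sobelGradient(sl)
  # ideal symmetric step: equal gradient mass at intensities 0 and 10 -> T = 5
  expect_equal(leafletThreshold(sl, G), 5)
  # shifting intensities by +c shifts T by exactly +c
  expect_equal(leafletThreshold(sl + 3, G), 8)
  # all-zero gradient: undefined, defer to parent
  expect_true(is.na(leafletThreshold(matrix(1, 5, 5), matrix(0, 5, 5))))
  expect_error(leafletThreshold(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("threshold fields adapt to regional contrast", {
  set.seed(7)
  mkSlice <- function(scale) {
    sl <- matrix(2, 64, 64)
    for (cc in list(c(16, 16), c(48, 16), c(16, 48), c(48, 48), c(32, 32))) {
      for (y in 1:64) for (x in 1:64) {
        d2 <- (x - cc[1])^2 + (y - cc[2])^2
        if (d2 <= 16) sl[y, x] <- sl[y, x] + 100 * exp(-d2 / 8)
      }
    }
    sl * scale
  }
  p <- ratsParams(leafletSize = 16, minNoise = 1, scalingFactor = 3,
                  minDepth = 3)

  # uniform objects on a uniform background: near-constant field ~ global T
  sl <- mkSlice(1)
  tf <- buildThresholdField(sl, p)
  G <- sobelGradient(sl)
  globalT <- sum(G^2 * sl) / sum(G^2)
  expect_lt(diff(range(tf@field)) / globalT, 0.5)
  expect_lt(abs(median(tf@field) - globalT) / globalT, 0.3)
  # field bounded by the slice intensity range
  expect_true(all(tf@field >= min(sl) & tf@field <= max(sl)))

  # left half 2x brighter (objects and background): left thresholds ~ 2x right
  half <- cbind(mkSlice(2)[, 1:32], mkSlice(1)[, 33:64])
  tfh <- buildThresholdField(half, p)
  ratio <- mean(tfh@field[, 1:16]) / mean(tfh@field[, 49:64])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)

  # constant slice: fallback to the slice median, empty mask
  tc <- buildThresholdField(matrix(4, 32, 32), p)
  expect_true(all(tc@field == 4))
  expect_false(any(matrix(4, 32, 32) > tc@field))
})

test_that("pseudo-3D mask is shift-equivariant and slice-consistent", {
  set.seed(8)
  sl <- matrix(2, 32, 32)
  sl[10:14, 10:14] <- sl[10:14, 10:14] + 60
  sl[22:25, 20:24] <- sl[22:25, 20:24] + 40
  a <- array(sl, dim = c(32, 32, 4))  # identical slices
  v <- VolumeStack(a)
  p <- ratsParams(leafletSize = 8, minNoise = 1, minDepth = 3)
  m <- ratsMask(v, p)
  for (z in 2:4) expect_equal(m[, , z], m[, , 1])

  # shift equivariance: mask(volume + c) with recomputed thresholds
  m2 <- ratsMask(VolumeStack(a + 17), p)
  expect_identical(m, m2)

  expect_false(any(ratsMask(VolumeStack(array(0, dim = c(16, 16, 3))), p)))
  expect_error(ratsMask(v, p, reference = 9), "out of range")
})

test_that("RATS segments both objects where a global threshold fails", {
  # two-region slice with independent contrasts: a dim object on a dim half
  # and a bright object on a bright half
  sl <- matrix(0, 64, 64)
  sl[, 1:32] <- 5; sl[, 33:64] <- 120
  sl[14:18, 14:18] <- 30     # dim object, bright enough locally
  sl[14:18, 46:50] <- 230    # bright object
  p <- ratsParams(leafletSize = 16, minNoise = 0.5, minDepth = 4)
  tf <- buildThresholdField(sl, p)
  mask <- sl > tf@field
  dimHit <- any(mask[14:18, 14:18])
  brightHit <- any(mask[14:18, 46:50])
  expect_true(dimHit && brightHit)

  # brute-force search: no single global threshold catches both objects
  # without also flooding the bright background half
  hasGlobal <- any(vapply(sort(unique(as.numeric(sl))), function(t) {
    m <- sl > t
    any(m[14:18, 14:18]) && any(m[14:18, 46:50]) && !any(m[1:13, 33:64])
  }, logical(1)))
  expect_false(hasGlobal)
})

test_that("overmask parameters are strictly more permissive", {
  p <- ratsParams(minNoise = 40)
  expect_equal(overmaskParams(p)$minNoise, 20)
  expect_equal(overmaskParams(p)$leafletSize, p$leafletSize)
})
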