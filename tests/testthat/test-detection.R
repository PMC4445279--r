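# Candidate generation, classification, mean shift, merging.

test_that("local maxima match a brute-force neighborhood scan", {
  set.seed(11)
  for (rep in 1:3) {
    a <- array(runif(20 * 20 * 8), dim = c(20, 20, 8))
    mask <- array(runif(length(a)) > 0.3, dim = dim(a))
    got <- markers(localMaxima(VolumeStack(a), mask, c(7, 7, 5)))
    want <- bruteLocalMaxima(a, mask, c(7, 7, 5))
    want <- want[order(want[, 3], want[, 2], want[, 1]), , drop = FALSE]
    expect_equal(as.matrix(got[, c("x", "y", "z")]),
                 unname(want[, 1:3, drop = FALSE]), ignore_attr = TRUE)
  }
})

test_that("isolated peaks, empty masks and plateaus behave as specified", {
  v <- makeBlobStack(data.frame(x = 10, y = 12, z = 3), peaks = 100,
                     dims = c(24, 24, 7))
  full <- array(TRUE, dim = dim(stackData(v)))
  ms <- localMaxima(v, full, c(7, 7, 5))
  expect_equal(nMarkers(ms), 1)
  expect_equal(unname(markerCoords(ms)[1, ]), c(10, 12, 3))

  expect_equal(nMarkers(localMaxima(v, array(FALSE, dim = dim(full)),
                                    c(7, 7, 5))), 0)

  # two adjacent equal maxima form one plateau; smallest (z, y, x) survives
  a <- array(0, dim = c(10, 10, 3))
  a[5, 5, 2] <- 9; a[5, 6, 2] <- 9
  ms2 <- localMaxima(VolumeStack(a), a > 0, c(7, 7, 3))
  expect_equal(nMarkers(ms2), 1)
  expect_equal(unname(markerCoords(ms2)[1, ]), c(4, 4, 1))

  expect_error(localMaxima(v, full, c(6, 7, 5)), "odd")
})

test_that("classification keeps what the model accepts", {
  v <- makeBlobStack(data.frame(x = c(8, 20), y = c(8, 20), z = c(3, 3)),
                     peaks = c(100, 90), dims = c(28, 28, 7))
  cand <- localMaxima(v, array(TRUE, dim = dim(stackData(v))), c(7, 7, 5))
  expect_equal(nMarkers(cand), 2)

  # degenerate models through the plugin surface: an output bias of +/-50
  # saturates the sigmoid, giving an always-positive / always-negative model
  fakeModel <- function(val) {
    set.seed(1)
    X <- matrix(c(rnorm(10, 0), rnorm(10, 6)), 20, 1)
    m <- trainMlp(X, rep(c(0, 1), each = 10), mlpConfig(seed = 1),
                  chain = algorithmChain("mean_intensity", "mlp"))
    m@W1[] <- 0
    m@W2[] <- 0
    m@W2[1, 1] <- if (val == 1) 50 else -50
    m
  }
  kept <- classifyCandidates(fakeModel(1), v, cand)
  expect_equal(nMarkers(kept), 2)
  expect_true(all(hasStatusVec(markers(kept)$status, "classified")))
  none <- classifyCandidates(fakeModel(0), v, cand)
  expect_equal(nMarkers(none), 0)
})

test_that("mean shift converges to blob centers and handles flat windows", {
  v <- makeBlobStack(data.frame(x = 11, y = 9, z = 3), peaks = 100,
                     dims = c(24, 24, 7))
  # start one voxel off the peak
  p <- meanShiftRefine(v, c(12, 10, 3), c(9, 9, 3), tol = 0.25, maxIter = 30)
  expect_equal(unname(p), c(11, 9, 3))

  # constant window: centroid is the geometric center, immediate convergence
  vc <- VolumeStack(array(5, dim = c(15, 15, 5)))
  expect_equal(unname(meanShiftRefine(vc, c(7, 7, 2))), c(7, 7, 2))

  # all-zero window: marker unchanged
  vz <- VolumeStack(array(0, dim = c(15, 15, 5)))
  expect_equal(unname(meanShiftRefine(vz, c(3, 4, 1))), c(3, 4, 1))
})

test_that("mean-shift refinement moves markers toward true centers", {
  gen <- generateScene(tinySceneParams(seed = 6))
  tc <- markerCoords(trueCenters(gen$scene))
  set.seed(6)
  # perturb true centers by up to 2 voxels in xy
  start <- tc
  start[, 1] <- pmax(0, start[, 1] + sample(-2:2, nrow(tc), TRUE))
  start[, 2] <- pmax(0, start[, 2] + sample(-2:2, nrow(tc), TRUE))
  ms <- MarkerSet(x = start[, 1], y = start[, 2], z = start[, 3])
  ref <- refineMarkers(gen$synapse, ms)
  dist0 <- sqrt(rowSums((start - tc)^2))
  dist1 <- sqrt(rowSums((markerCoords(ref) - tc)^2))
  expect_lte(mean(dist1), mean(dist0))
  expect_true(all(hasStatusVec(markers(ref)$status, "shifted")))
})

test_that("merging agrees with exhaustive agglomeration and its invariants", {
  vs <- c(80, 80, 400)
  # two markers 1 voxel apart -> one marker
  m <- mergeClose(MarkerSet(x = c(5, 6), y = c(5, 5), z = c(1, 1),
                            score = c(1, 3)), minSep = 3.5, voxelSize = vs)
  expect_equal(nMarkers(m), 1)
  expect_equal(markers(m)$x, 6)  # score-weighted centroid rounds toward 6

  # all pairwise >= minSep: unchanged
  far <- MarkerSet(x = c(0, 10, 20), y = c(0, 0, 0), z = c(0, 0, 0))
  expect_equal(nMarkers(mergeClose(far, minSep = 3.5, voxelSize = vs)), 3)

  # three collinear markers at spacing just under minSep: exhaustive
  # agglomeration merges the first tie pair (0,3) into 1.5 (rounds to 2);
  # the survivor then sits 4 > minSep from the third, so two markers remain
  tri <- MarkerSet(x = c(0, 3, 6), y = c(0, 0, 0), z = c(0, 0, 0),
                   score = c(1, 1, 1))
  mt <- mergeClose(tri, minSep = 3.5, voxelSize = vs)
  expect_equal(nMarkers(mt), 2)
  expect_equal(sort(markers(mt)$x), c(2, 6))

  # z distances are anisotropy-scaled (dz/dx = 5): |dz| = 1 is 5 voxels
  zm <- mergeClose(MarkerSet(x = c(5, 5), y = c(5, 5), z = c(1, 2)),
                   minSep = 3.5, voxelSize = vs)
  expect_equal(nMarkers(zm), 2)

  # merging never increases the count
  set.seed(12)
  rnd <- MarkerSet(x = sample(0:15, 20, TRUE), y = sample(0:15, 20, TRUE),
                   z = sample(0:3, 20, TRUE))
  rnd <- MarkerSet(unique(markers(rnd)[, c("x", "y", "z")]))
  mr <- mergeClose(rnd, minSep = 3, voxelSize = vs)
  expect_lte(nMarkers(mr), nMarkers(rnd))
  sc <- cbind(markerCoords(mr)[, 1:2], markerCoords(mr)[, 3] * 5)
  D <- as.matrix(dist(sc))
  expect_true(all(D[upper.tri(D)] >= 3 - 1.5))  # rounding can shave < 1.5
})
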