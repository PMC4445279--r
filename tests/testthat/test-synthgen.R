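# Synthetic confocal scene generator.

test_that("scenes are deterministic under a fixed seed and seed-sensitive", {
  p <- tinySceneParams(seed = 7)
  g1 <- generateScene(p)
  g2 <- generateScene(p)
  expect_identical(stackData(g1$synapse), stackData(g2$synapse))
  expect_identical(stackData(g1$morphology), stackData(g2$morphology))
  expect_identical(markers(trueCenters(g1$scene)),
                   markers(trueCenters(g2$scene)))

  g3 <- generateScene(tinySceneParams(seed = 8))
  expect_false(identical(stackData(g1$synapse), stackData(g3$synapse)))
  expect_equal(nMarkers(trueCenters(g3$scene)),
               nMarkers(trueCenters(g1$scene)))
})

test_that("scene structure matches its parameters", {
  p <- tinySceneParams(seed = 7)
  g <- generateScene(p)
  sc <- g$scene
  expect_equal(nMarkers(trueCenters(sc)), p$nSynapses)
  expect_equal(nMarkers(artifactCenters(sc)), p$artifactCount)
  expect_equal(dim(stackData(g$synapse)),
               c(p$shape[2], p$shape[3], p$shape[1]))

  # every true center lies on/near (<= 2 voxels from) the morphology mask
  tube <- morphologyMask(sc)
  tc <- markerCoords(trueCenters(sc))
  onTube <- vapply(seq_len(nrow(tc)), function(i)
    PunctaQuant:::nearMask(tube, tc[i, ], reachXy = 2, reachZ = 1),
    logical(1))
  expect_true(all(onTube))

  # artifacts are planted away from the tube
  ac <- markerCoords(artifactCenters(sc))
  offTube <- vapply(seq_len(nrow(ac)), function(i)
    PunctaQuant:::nearMask(tube, ac[i, ], reachXy = 8, reachZ = 2),
    logical(1))
  expect_false(any(offTube))

  # ground-truth labels cover each center's voxel with its own id
  lab <- trueLabels(sc)
  d <- dim(lab)
  ids <- lab[PunctaQuant:::coordToLinear(d, tc[, 1], tc[, 2], tc[, 3])]
  expect_equal(ids, seq_len(nrow(tc)))

  # an impossible request errors rather than overlapping everything
  expect_error(generateScene(tinySceneParams(seed = 1, nSynapses = 4000)),
               "cannot place")
})

test_that("noise-free isolated blobs peak exactly at the true centers", {
  p <- tinySceneParams(seed = 10, noiseSigma = 0, clumpFraction = 0,
                       artifactCount = 0)
  g <- generateScene(p)
  a <- stackData(g$synapse)
  d <- dim(a)
  tc <- markerCoords(trueCenters(g$scene))
  # brute-force neighborhood scan: strict local maximum at every center
  for (i in seq_len(nrow(tc))) {
    x <- tc[i, 1]; y <- tc[i, 2]; z <- tc[i, 3]
    ys <- max(1, y):min(d[1], y + 2); xs <- max(1, x):min(d[2], x + 2)
    zs <- max(1, z):min(d[3], z + 2)
    nb <- a[ys, xs, zs]
    cv <- a[y + 1, x + 1, z + 1]
    expect_equal(sum(nb == cv), 1)
    expect_true(all(nb[nb != cv] < cv))
  }
})

test_that("blob-integrated intensity matches the analytic Gaussian mass", {
  p <- tinySceneParams(seed = 11, noiseSigma = 0, clumpFraction = 0,
                       artifactCount = 0, backgroundBase = 0,
                       backgroundGradient = 0, nSynapses = 4,
                       minSeparation = 30, shape = c(10, 80, 80))
  g <- generateScene(p)
  a <- stackData(g$synapse)
  tc <- markers(trueCenters(g$scene))
  analytic <- (2 * pi)^(3 / 2) * p$xySigma^2 * p$zSigma
  # restrict to blobs whose 3-sigma support is fully inside the stack
  interior <- tc$z >= 3 & tc$z <= 6 & tc$x >= 6 & tc$x <= 73 &
    tc$y >= 6 & tc$y <= 73
  expect_gte(sum(interior), 1)
  for (i in which(interior)) {
    # sum over a generous box around the blob (blobs are well separated)
    xs <- max(0, tc$x[i] - 6):min(79, tc$x[i] + 6)
    ys <- max(0, tc$y[i] - 6):min(79, tc$y[i] + 6)
    zs <- max(0, tc$z[i] - 4):min(9, tc$z[i] + 4)
    mass <- sum(a[ys + 1, xs + 1, zs + 1])
    expect_equal(mass, tc$score[i] * analytic, tolerance = 0.02)
  }
})

test_that("training ROI sampling respects labels and exclusion radii", {
  g <- generateScene(tinySceneParams(seed = 12))
  rois <- sampleTrainingRois(g$scene, g$synapse, nPos = 10, nNeg = 10,
                             seed = 2)
  expect_length(rois, 20)
  labs <- vapply(rois, roiLabel, "")
  expect_equal(sum(labs == "positive"), 10)

  tc <- markerCoords(trueCenters(g$scene))
  for (r in rois[labs == "negative"]) {
    c0 <- r@center
    dxy <- sqrt((tc[, 1] - c0[1])^2 + (tc[, 2] - c0[2])^2)
    expect_gte(min(dxy), 3)
  }
  # positives sit exactly on true centers
  key <- paste(tc[, 1], tc[, 2], tc[, 3])
  for (r in rois[labs == "positive"])
    expect_true(paste(r@center[1], r@center[2], r@center[3]) %in% key)

  expect_error(sampleTrainingRois(g$scene, g$synapse, nPos = 1000),
               "positives requested")
  onlyPos <- sampleTrainingRois(g$scene, g$synapse, nPos = 5, nNeg = 0,
                                seed = 3)
  expect_length(onlyPos, 5)
})
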