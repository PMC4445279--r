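# Connected components, contour concavity and marker-guided splitting.

test_that("26-connected labeling agrees with flood fill and filters noise", {
  # corner contact connects under 26-connectivity
  m <- array(FALSE, dim = c(5, 5, 2))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_equal(nObjects(connectedComponents26(m, minSize = 1)), 1)

  # the < 8 voxel noise rule: 7 voxels removed, 8 retained
  m7 <- array(FALSE, dim = c(10, 10, 3))
  m7[2, 2:8, 2] <- TRUE                      # 7 voxels
  expect_equal(nObjects(connectedComponents26(m7)), 0)
  m8 <- m7; m8[2, 9, 2] <- TRUE              # 8 voxels
  o8 <- connectedComponents26(m8)
  expect_equal(nObjects(o8), 1)
  expect_equal(objectStats(o8)$voxel_count, 8L)

  # random masks against the brute-force oracle (label sets must partition
  # identically; renumbering may differ)
  set.seed(13)
  for (rep in 1:5) {
    mask <- array(runif(15 * 15 * 6) > 0.7, dim = c(15, 15, 6))
    got <- labelArray(connectedComponents26(mask, minSize = 1))
    want <- floodFill26(mask)
    expect_equal(sum(got > 0), sum(want > 0))
    # same partition: each oracle component maps to exactly one label
    for (L in seq_len(max(want))) {
      expect_equal(length(unique(got[want == L])), 1L)
    }
    expect_equal(max(got), max(want))
  }

  # labels are renumbered by decreasing size
  two <- array(FALSE, dim = c(12, 12, 2))
  two[2:3, 2:3, 1:2] <- TRUE     # 8 voxels
  two[7:10, 7:10, 1] <- TRUE     # 16 voxels
  st <- objectStats(connectedComponents26(two))
  expect_equal(st$voxel_count, c(16L, 8L))
  expect_equal(st$label, c(1L, 2L))
})

test_that("MIP projection keeps column membership", {
  vox <- data.frame(x = c(3, 3, 4, 9), y = c(2, 2, 2, 5), z = c(0, 1, 1, 2))
  pr <- mipProject(vox)
  expect_equal(sum(pr$mask), 3)          # (3,2), (4,2), (9,5)
  expect_lte(sum(pr$mask), nrow(vox))    # area <= voxel count
  # single-slice object: projection identical to that slice
  single <- data.frame(x = c(0, 1), y = c(0, 0), z = 0)
  expect_equal(sum(mipProject(single)$mask), 2)
  # stacking the same slice twice leaves the projection unchanged
  double <- rbind(single, transform(single, z = 1))
  expect_equal(mipProject(double)$mask, mipProject(single)$mask)
  expect_error(mipProject(data.frame(x = numeric(), y = numeric(),
                                     z = numeric())), "empty")
})

test_that("contour tracing yields ordered closed boundaries with Eq-style concavity", {
  # 5x5 filled square: 16 boundary pixels
  sq <- matrix(TRUE, 5, 5)
  ct <- traceContour(sq)
  expect_equal(nrow(ct), 16)
  expect_equal(ct$x[1], 0); expect_equal(ct$y[1], 0)  # canonical start
  # every boundary pixel appears exactly once
  expect_equal(anyDuplicated(ct[, c("x", "y")]), 0L)

  # w and C against the brute-force window count
  for (i in seq_len(nrow(ct)))
    expect_equal(ct$w[i], bruteWindowCount(sq, ct$x[i], ct$y[i]))
  n <- nrow(ct)
  for (i in seq_len(n)) {
    expect_equal(ct$C[i], ct$w[((i - 2) %% n) + 1] + ct$w[i] +
                            ct$w[(i %% n) + 1])
  }

  # straight edge of a large half-plane: interior edge points have w = 15,
  # C = 45
  hp <- matrix(FALSE, 12, 12); hp[5:12, ] <- TRUE
  cth <- traceContour(hp)
  edge <- cth[cth$y == 4 & cth$x >= 3 & cth$x <= 8, ]
  expect_true(all(edge$w == 15))
  expect_true(all(edge$C == 45))

  # dumbbell: concave notch scores above straight edge above convex corner
  db <- dumbbellMask()
  ctd <- traceContour(db)
  notch <- max(ctd$C[ctd$x %in% 10:12])      # waist region
  convex <- min(ctd$C)
  expect_gt(notch, 45)
  expect_gt(45, convex)

  expect_error(traceContour(matrix(FALSE, 3, 3)), "empty")
  # single pixel object: a one-point closed contour
  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_equal(nrow(traceContour(single)), 1)
})

test_that("split energy follows E = C(i) C(j) / d(i, j)", {
  pi_ <- list(index = 1, x = 0, y = 0, C = 45)
  pj <- list(index = 2, x = 10, y = 0, C = 45)
  e <- splitEnergy(pi_, pj)
  expect_equal(e$E, 202.5)
  expect_equal(e$d, 10)
  # symmetry
  expect_equal(splitEnergy(pj, pi_)$E, e$E)
  # doubling the distance halves the energy
  pj2 <- list(index = 3, x = 20, y = 0, C = 45)
  expect_equal(splitEnergy(pi_, pj2)$E, e$E / 2)
  expect_error(splitEnergy(pi_, pi_), "coincident")
})

test_that("findSplit separates dumbbell lobes through the waist notches", {
  db <- dumbbellMask()
  ct <- traceContour(db)
  mk <- rbind(c(6, 7), c(15, 7))  # one marker per lobe (0-based)
  sp <- findSplit(ct, db, mk, target = 1)
  expect_false(is.null(sp))
  # the chord passes through the waist (x around 10-12)
  expect_true(all(ct$x[c(sp$i, sp$j)] >= 9 & ct$x[c(sp$i, sp$j)] <= 13))
  # each side contains exactly one marker
  h <- nrow(db)
  cut <- db
  cut[sp$chord[, 1] * h + sp$chord[, 2] + 1L] <- FALSE
  lab <- PunctaQuant:::label2d8(cut)
  l1 <- lab[mk[1, 1] * h + mk[1, 2] + 1L]
  l2 <- lab[mk[2, 1] * h + mk[2, 2] + 1L]
  expect_true(l1 > 0 && l2 > 0 && l1 != l2)

  # brute force over all contour pairs: the returned pair maximizes E among
  # separating chords anchored at the chosen A
  A <- sp$i
  Es <- c()
  best <- -Inf
  for (j in seq_len(nrow(ct))) {
    if (j == A) next
    d <- sqrt((ct$x[A] - ct$x[j])^2 + (ct$y[A] - ct$y[j])^2)
    if (d == 0) next
    chord <- PunctaQuant:::bresenhamLine(ct$x[A], ct$y[A], ct$x[j], ct$y[j])
    cut <- db
    cut[chord[, 1] * h + chord[, 2] + 1L] <- FALSE
    if (!cut[mk[1, 1] * h + mk[1, 2] + 1L] ||
        !cut[mk[2, 1] * h + mk[2, 2] + 1L]) next
    lab <- PunctaQuant:::label2d8(cut)
    if (lab[mk[1, 1] * h + mk[1, 2] + 1L] !=
        lab[mk[2, 1] * h + mk[2, 2] + 1L])
      best <- max(best, ct$C[A] * ct$C[j] / d)
  }
  expect_equal(sp$E, best)

  # markers coincident in projection: unsplittable
  expect_null(findSplit(ct, db, rbind(c(6, 7), c(6, 7)), 1))

  # convex disc with two separated markers: some chord still separates
  disc <- matrix(FALSE, 11, 11)
  for (y in 1:11) for (x in 1:11)
    if ((x - 6)^2 + (y - 6)^2 <= 16) disc[y, x] <- TRUE
  ctd <- traceContour(disc)
  spd <- findSplit(ctd, disc, rbind(c(3, 5), c(8, 5)), target = 1)
  expect_false(is.null(spd))
})

test_that("recursive splitting conserves voxels with one marker per child", {
  db <- dumbbellMask()
  vdf <- maskToVoxelDf(db)
  vdf <- rbind(vdf, transform(vdf, z = 1))  # two-slice object
  mk <- data.frame(id = 1:2, x = c(6, 15), y = c(7, 7), z = c(0, 0))
  kids <- recursiveSplit(vdf, mk)
  expect_length(kids, 2)
  expect_false(any(vapply(kids, `[[`, TRUE, "unsplittable")))
  # disjoint, exhaustive partition
  allv <- do.call(rbind, lapply(kids, `[[`, "voxels"))
  key <- function(d) paste(d$x, d$y, d$z)
  expect_equal(sort(key(allv)), sort(key(vdf)))
  expect_equal(anyDuplicated(key(allv)), 0L)
  # each child contains exactly its marker
  for (k in kids) {
    inside <- vapply(seq_len(nrow(mk)), function(i)
      any(k$voxels$x == mk$x[i] & k$voxels$y == mk$y[i] &
            k$voxels$z == mk$z[i]), logical(1))
    expect_equal(sum(inside), 1L)
    expect_true(inside[mk$id == k$marker_id])
  }

  # single marker: object unchanged
  one <- recursiveSplit(vdf, mk[1, ])
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]$voxels), nrow(vdf))
})

test_that("three collinear fused blobs split into three children, end first", {
  m <- matrix(FALSE, 13, 30)
  for (cx in c(6, 15, 24)) {
    for (y in 1:13) for (x in 1:30)
      if ((x - cx)^2 + (y - 7)^2 <= 14) m[y, x] <- TRUE
  }
  vdf <- maskToVoxelDf(m)
  mk <- data.frame(id = 1:3, x = c(5, 14, 23), y = c(6, 6, 6), z = 0)
  kids <- recursiveSplit(vdf, mk)
  expect_length(kids, 3)
  expect_false(any(vapply(kids, `[[`, TRUE, "unsplittable")))
  # STEP-4 ordering: the first separated marker is an end one (max sum dist)
  expect_true(kids[[1]]$marker_id %in% c(1, 3))
  # conservation
  allv <- do.call(rbind, lapply(kids, `[[`, "voxels"))
  expect_equal(nrow(allv), nrow(vdf))
  expect_equal(sort(vapply(kids, `[[`, 0, "marker_id")), 1:3)
})

test_that("splitObjects rebuilds labels and quantify summarizes sizes", {
  db <- dumbbellMask()
  arr <- array(FALSE, dim = c(15, 23, 3))
  arr[, , 2] <- db
  obj <- connectedComponents26(arr)
  expect_equal(nObjects(obj), 1)
  mk <- MarkerSet(x = c(6, 15), y = c(7, 7), z = c(1, 1))
  sp <- splitObjects(obj, mk)
  expect_equal(nObjects(sp), 2)
  st <- objectStats(sp)
  expect_true(all(st$from_split))
  expect_equal(sum(st$voxel_count), sum(db))
  expect_equal(sort(st$marker_id), c(1L, 2L))

  q <- quantifyObjects(sp)
  expect_equal(q$count, 2)
  expect_equal(q$mean, mean(st$voxel_count))

  # the in-range filter
  fake <- new("LabeledObjects", labels = array(0L, dim = c(2, 2, 1)),
              stats = data.frame(label = 1:3, voxel_count = c(8, 20, 1200),
                                 cx = 0, cy = 0, cz = 0, x0 = 0, y0 = 0,
                                 z0 = 0, x1 = 0, y1 = 0, z1 = 0,
                                 marker_id = NA_integer_,
                                 unsplittable = FALSE, from_split = FALSE),
              voxelSize = c(80, 80, 400))
  qf <- quantifyObjects(fake)
  expect_equal(qf$count, 2)
  expect_equal(qf$min, 8)
  expect_equal(qf$max, 20)
  q0 <- quantifyObjects(new("LabeledObjects",
                            labels = array(0L, dim = c(2, 2, 1)),
                            stats = PunctaQuant:::emptyObjectStats(),
                            voxelSize = c(80, 80, 400)))
  expect_equal(q0$count, 0)
})
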