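# Shared fixtures and independent oracles, all built in code.

# Stack of anisotropic Gaussian blobs at integer centers (data.frame x,y,z).
makeBlobStack <- function(centers, peaks, dims = c(32, 32, 8),
                          sigmaXy = 1.6, sigmaZ = 0.8, bg = 0,
                          voxelSize = c(80, 80, 400)) {
  a <- array(bg, dim = dims)  # dims = (Y, X, Z)
  for (i in seq_len(nrow(centers))) {
    for (z in seq_len(dims[3])) for (y in seq_len(dims[1]))
      for (x in seq_len(dims[2])) {
        dx <- (x - 1) - centers$x[i]; dy <- (y - 1) - centers$y[i]
        dz <- (z - 1) - centers$z[i]
        a[y, x, z] <- a[y, x, z] + peaks[i] *
          exp(-(dx^2 + dy^2) / (2 * sigmaXy^2) - dz^2 / (2 * sigmaZ^2))
      }
  }
  VolumeStack(a, voxelSize = voxelSize)
}

# Small synthetic scene for module-level tests (seconds, not minutes).
tinySceneParams <- function(seed = 5, ...) {
  p <- sceneParams(shape = c(8, 96, 96), nSynapses = 15, artifactCount = 3,
                   nBranches = 2, branchSteps = 180, seed = seed)
  utils::modifyList(p, list(...))
}

# Brute-force masked local maxima: compare every voxel to its full
# clipped neighborhood.
bruteLocalMaxima <- function(a, mask, nb = c(7, 7, 5)) {
  d <- dim(a)
  h <- (nb - 1) / 2
  out <- NULL
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1])) {
    if (!mask[y, x, z]) next
    ys <- max(1, y - h[2]):min(d[1], y + h[2])
    xs <- max(1, x - h[1]):min(d[2], x + h[1])
    zs <- max(1, z - h[3]):min(d[3], z + h[3])
    if (a[y, x, z] == max(a[ys, xs, zs]))
      out <- rbind(out, c(x - 1, y - 1, z - 1, a[y, x, z]))
  }
  out
}

# Brute-force 26-connected flood-fill labeling of a 3D mask.
floodFill26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      p0 <- p - 1L
      py <- p0 %% d[1]; px <- (p0 %/% d[1]) %% d[2]; pz <- p0 %/% (d[1] * d[2])
      for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        ny <- py + dy; nx <- px + dx; nz <- pz + dz
        if (ny < 0 || ny >= d[1] || nx < 0 || nx >= d[2] ||
            nz < 0 || nz >= d[3]) next
        q <- 1L + ny + d[1] * (nx + d[2] * nz)
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

hasStatusVec <- function(status, flag) PunctaQuant:::hasStatus(status, flag)

# Foreground count in the clipped 5x5 window at 0-based (x, y).
bruteWindowCount <- function(mask, x, y) {
  h <- nrow(mask); w <- ncol(mask)
  xr <- max(0, x - 2):min(w - 1, x + 2)
  yr <- max(0, y - 2):min(h - 1, y + 2)
  sum(mask[yr + 1, xr + 1, drop = FALSE])
}

# Dumbbell: two discs of radius ~4.7 px whose overlap forms a thin waist.
dumbbellMask <- function() {
  m <- matrix(FALSE, 15, 23)
  for (y in 1:15) for (x in 1:23) {
    if ((x - 7)^2 + (y - 8)^2 <= 22 || (x - 16)^2 + (y - 8)^2 <= 22)
      m[y, x] <- TRUE
  }
  m
}

maskToVoxelDf <- function(mask2d, z = 0) {
  w <- which(mask2d, arr.ind = TRUE)
  data.frame(x = w[, 2] - 1L, y = w[, 1] - 1L, z = z)
}

# Separable two-cloud ROI set in feature space: tiny constant-intensity ROIs
# whose mean differs by class (exercises the chain machinery end to end).
separableRoiSet <- function(n = 20, seed = 3) {
  set.seed(seed)
  rois <- list()
  for (i in seq_len(n)) {
    lvl <- 100 + rnorm(1, sd = 2)
    rois[[i]] <- new("Roi3D",
      data = array(lvl + rnorm(9 * 9 * 3, sd = 1), dim = c(9, 9, 3)),
      center = c(4L, 4L, 1L), label = "positive")
  }
  for (i in seq_len(n)) {
    lvl <- 10 + rnorm(1, sd = 2)
    rois[[n + i]] <- new("Roi3D",
      data = array(lvl + rnorm(9 * 9 * 3, sd = 1), dim = c(9, 9, 3)),
      center = c(4L, 4L, 1L), label = "negative")
  }
  rois
}
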