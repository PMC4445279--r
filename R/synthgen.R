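# Seeded synthetic two-channel confocal scenes with ground truth.
#
# The generator emulates the image properties the detector must cope with:
# bright oval puncta whose xy extent exceeds their z extent (anisotropic
# PSF), fused clumps of 2-3 puncta, dim staining artifacts floating off the
# neuron, smooth regional background variation, additive Gaussian noise, and
# a tube-like (branched random walk) morphology channel. Identical seeds give
# bit-identical scenes.

#' Synthetic scene parameters
#'
#' Defaults define the package's benchmark scene: a 256 x 256 x 16 stack with
#' 150 synapses (30\% of them in fused clumps of 2-3), 10 dim off-neuron
#' artifacts at 0.3 x peak intensity, a smooth background gradient, and
#' additive Gaussian noise with sd equal to 10\% of the median peak
#' intensity. Intensities are on a 16-bit-compatible integer scale.
#'
#' @param shape \code{(Z, Y, X)} stack extents.
#' @param nSynapses number of true synapses.
#' @param xySigma,zSigma Gaussian blob sd in xy / z voxels (xy >= z reflects
#'   the anisotropic voxel).
#' @param peakIntensity \code{(min, max)} of per-synapse peak intensities.
#' @param clumpFraction fraction of synapses placed in fused clumps.
#' @param clumpSizes allowed clump sizes (2 and/or 3).
#' @param artifactCount number of dim artifacts planted off the morphology.
#' @param artifactIntensityFactor artifact peak as a fraction of a synapse
#'   peak, in (0, 1).
#' @param backgroundGradient amplitude of the smooth additive background.
#' @param backgroundBase constant background offset.
#' @param noiseSigma additive Gaussian noise sd in the synapse channel
#'   (default 20, i.e. 10\% of the median peak 202.5, rounded).
#' @param morphologyNoiseSigma noise sd in the morphology channel (default
#'   8, about 5\% of the tube intensity: membrane markers are imaged at
#'   high signal-to-noise and serve only as a binary structure reference).
#' @param tubeRadiusXy,tubeRadiusZ morphology tube radius in xy voxels and z
#'   slices.
#' @param nBranches number of random-walk branches in the morphology.
#' @param branchSteps steps per branch walk.
#' @param minSeparation minimum anisotropy-scaled distance between synapse
#'   seats (clump members are closer by construction).
#' @param voxelSize \code{(dx, dy, dz)} nm.
#' @param seed RNG seed; the scene is a pure function of the parameters.
#' @return A validated named list.
#' @export
sceneParams <- function(shape = c(16, 256, 256), nSynapses = 150,
                        xySigma = 1.6, zSigma = 0.8,
                        peakIntensity = c(150, 255), clumpFraction = 0.3,
                        clumpSizes = 2:3, artifactCount = 10,
                        artifactIntensityFactor = 0.3,
                        backgroundGradient = 8, backgroundBase = 2,
                        noiseSigma = 20, morphologyNoiseSigma = 8,
                        tubeRadiusXy = 5, tubeRadiusZ = 1,
                        nBranches = 5, branchSteps = 500,
                        minSeparation = 10, voxelSize = c(80, 80, 400),
                        seed = 42) {
  stopifnot(length(shape) == 3, all(shape >= 1), nSynapses >= 0,
            xySigma >= zSigma, zSigma > 0,
            clumpFraction >= 0, clumpFraction <= 1,
            all(clumpSizes %in% 2:3), artifactCount >= 0,
            artifactIntensityFactor > 0, artifactIntensityFactor < 1,
            noiseSigma >= 0, morphologyNoiseSigma >= 0, minSeparation > 0)
  as.list(environment())
}

#' Generate a synthetic two-channel confocal scene
#'
#' The synapse channel is the sum of anisotropic Gaussian blobs at the true
#' centers (clump members spaced 1.0-1.5 x \code{xySigma} apart so their
#' blobs fuse), dim artifact blobs planted away from the morphology, a smooth
#' background gradient, and Gaussian noise; the morphology channel renders
#' the branched tube mask with the same noise model. Blobs are truncated at
#' 3 sigma (rounded up to whole voxels). Ground-truth labels assign each
#' blob voxel to the nearest center under the blob covariance (Mahalanobis).
#'
#' @param params a \code{\link{sceneParams}} list.
#' @return List with components \code{synapse} and \code{morphology}
#'   (\linkS4class{VolumeStack}s) and \code{scene}
#'   (\linkS4class{SyntheticScene}).
#' @export
generateScene <- function(params = sceneParams()) {
  withSeed(params$seed, generateSceneImpl(params))
}

generateSceneImpl <- function(p) {
  Z <- p$shape[1]; Y <- p$shape[2]; X <- p$shape[3]
  dims <- c(Y, X, Z)
  zf <- p$voxelSize[3] / p$voxelSize[1]

  tube <- makeTubeMask(p)
  tubeVox <- which(tube)
  if (!length(tubeVox)) stop("degenerate morphology: empty tube mask",
                             call. = FALSE)
  tubeCo <- linearToCoord(dims, tubeVox)
  zok <- tubeCo[, "z"] >= 1 & tubeCo[, "z"] <= Z - 2
  seatPool <- tubeCo[zok, , drop = FALSE]

  # ---- clump structure ----
  nClumped <- round(p$clumpFraction * p$nSynapses)
  clumpSz <- integer()
  while (sum(clumpSz) < nClumped) {
    clumpSz <- c(clumpSz, if (length(p$clumpSizes) > 1)
      sample(p$clumpSizes, 1) else p$clumpSizes)
  }
  if (sum(clumpSz) > nClumped && length(clumpSz))
    clumpSz[length(clumpSz)] <- max(2, clumpSz[length(clumpSz)] -
                                      (sum(clumpSz) - nClumped))
  nIso <- p$nSynapses - sum(clumpSz)
  if (nIso < 0) { clumpSz <- clumpSz[-length(clumpSz)]; nIso <- p$nSynapses - sum(clumpSz) }
  groupSizes <- c(rep(1L, nIso), clumpSz)

  # ---- place group seats on the tube, mutually >= minSeparation apart ----
  seats <- matrix(numeric(0), 0, 3)
  tries <- 0
  while (nrow(seats) < length(groupSizes)) {
    tries <- tries + 1
    if (tries > 200000)
      stop("cannot place synapses without total overlap: too many for shape",
           call. = FALSE)
    cand <- seatPool[sample(nrow(seatPool), 1), ]
    if (nrow(seats)) {
      d <- sqrt((seats[, 1] - cand["x"])^2 + (seats[, 2] - cand["y"])^2 +
                (zf * (seats[, 3] - cand["z"]))^2)
      if (min(d) < p$minSeparation) next
    }
    seats <- rbind(seats, cand)
  }

  # ---- expand clumps: integer xy offsets with norm in [1, 1.5] x xySigma ----
  lo <- 1.0 * p$xySigma; hi <- 1.5 * p$xySigma
  offCand <- expand.grid(dx = -3:3, dy = -3:3)
  offCand <- offCand[{ n <- sqrt(offCand$dx^2 + offCand$dy^2)
                       n >= lo & n <= hi }, ]
  centers <- matrix(numeric(0), 0, 3)
  for (g in seq_along(groupSizes)) {
    prev <- seats[g, ]
    centers <- rbind(centers, prev)
    for (k in seq_len(groupSizes[g] - 1)) {
      for (t in seq_len(200)) {
        o <- offCand[sample(nrow(offCand), 1), ]
        nxt <- c(prev[1] + o$dx, prev[2] + o$dy, prev[3])
        inb <- nxt[1] >= 0 && nxt[1] < X && nxt[2] >= 0 && nxt[2] < Y
        fresh <- !any(centers[, 1] == nxt[1] & centers[, 2] == nxt[2] &
                        centers[, 3] == nxt[3])
        nearTube <- nearMask(tube, nxt, reachXy = 2)
        if (inb && fresh && nearTube) break
      }
      centers <- rbind(centers, nxt)
      prev <- nxt
    }
  }
  rownames(centers) <- NULL
  colnames(centers) <- c("x", "y", "z")

  # ---- artifacts: dim blobs far from the tube and the synapses ----
  arts <- matrix(numeric(0), 0, 3)
  tries <- 0
  while (nrow(arts) < p$artifactCount && tries < 200000) {
    tries <- tries + 1
    cand <- c(sample(0:(X - 1), 1), sample(0:(Y - 1), 1),
              sample(1:(Z - 2), 1))
    if (nearMask(tube, cand, reachXy = 8, reachZ = 2)) next
    d <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 +
              (zf * (centers[, 3] - cand[3]))^2)
    if (length(d) && min(d) < p$minSeparation) next
    if (nrow(arts)) {
      da <- sqrt((arts[, 1] - cand[1])^2 + (arts[, 2] - cand[2])^2 +
                 (zf * (arts[, 3] - cand[3]))^2)
      if (min(da) < p$minSeparation) next
    }
    arts <- rbind(arts, cand)
  }
  colnames(arts) <- c("x", "y", "z")

  # ---- render ----
  syn <- array(0, dim = dims)
  labels <- array(0L, dim = dims)
  bestM <- array(Inf, dim = dims)
  rx <- ceiling(3 * p$xySigma); rz <- ceiling(3 * p$zSigma)
  ox <- -rx:rx; oz <- -rz:rz
  grid <- expand.grid(dy = ox, dx = ox, dz = oz)
  gauss <- exp(-(grid$dx^2 + grid$dy^2) / (2 * p$xySigma^2) -
                 grid$dz^2 / (2 * p$zSigma^2))
  mah <- sqrt((grid$dx^2 + grid$dy^2) / p$xySigma^2 +
                grid$dz^2 / p$zSigma^2)

  peaks <- stats::runif(nrow(centers), p$peakIntensity[1], p$peakIntensity[2])
  for (i in seq_len(nrow(centers))) {
    gx <- centers[i, 1] + grid$dx; gy <- centers[i, 2] + grid$dy
    gz <- centers[i, 3] + grid$dz
    inb <- gx >= 0 & gx < X & gy >= 0 & gy < Y & gz >= 0 & gz < Z
    idx <- coordToLinear(dims, gx[inb], gy[inb], gz[inb])
    syn[idx] <- syn[idx] + peaks[i] * gauss[inb]
    lb <- mah[inb] <= 3 & mah[inb] < bestM[idx]
    labels[idx[lb]] <- i
    bestM[idx[lb]] <- mah[inb][lb]
  }
  artPeaks <- p$artifactIntensityFactor *
    stats::runif(nrow(arts), p$peakIntensity[1], p$peakIntensity[2])
  for (i in seq_len(nrow(arts))) {
    gx <- arts[i, 1] + grid$dx; gy <- arts[i, 2] + grid$dy
    gz <- arts[i, 3] + grid$dz
    inb <- gx >= 0 & gx < X & gy >= 0 & gy < Y & gz >= 0 & gz < Z
    idx <- coordToLinear(dims, gx[inb], gy[inb], gz[inb])
    syn[idx] <- syn[idx] + artPeaks[i] * gauss[inb]
  }

  bg <- p$backgroundBase + p$backgroundGradient *
    outer(0.4 * (0:(Y - 1)) / max(1, Y - 1),
          0.6 * (0:(X - 1)) / max(1, X - 1), "+")
  syn <- syn + as.numeric(bg)  # recycles over z
  if (p$noiseSigma > 0)
    syn <- syn + correlatedNoise(dims, p$noiseSigma)
  syn <- array(pmin(pmax(round(syn), 0), 65535), dim = dims)

  morph <- array(as.numeric(bg), dim = dims) + 170 * tube
  if (p$morphologyNoiseSigma > 0)
    morph <- morph + correlatedNoise(dims, p$morphologyNoiseSigma)
  morph <- array(pmin(pmax(round(morph), 0), 65535), dim = dims)

  trueCenters <- MarkerSet(x = centers[, 1], y = centers[, 2],
                           z = centers[, 3], score = peaks, status = "")
  artifactCenters <- if (nrow(arts))
    MarkerSet(x = arts[, 1], y = arts[, 2], z = arts[, 3],
              score = artPeaks, status = "") else MarkerSet()
  scene <- new("SyntheticScene", trueCenters = trueCenters,
               trueLabels = labels, morphologyMask = tube,
               artifactCenters = artifactCenters, params = p)
  list(synapse = VolumeStack(syn, p$voxelSize, "synapse"),
       morphology = VolumeStack(morph, p$voxelSize, "morphology"),
       scene = scene)
}

# Gaussian noise with xy spatial correlation (sigma-2 Gaussian smoothing,
# 9 x 9 support), rescaled so the marginal sd is `sigma`. Deconvolved,
# frame-averaged confocal stacks have smooth, spatially correlated noise;
# iid pixel noise would put unrealistic gradient energy into flat regions.
correlatedNoise <- function(dims, sigma) {
  n <- array(stats::rnorm(prod(dims)), dim = dims)
  r <- 4L
  k <- exp(-(-r:r)^2 / (2 * 2^2)); k <- k / sum(k)
  for (axis in 1:2) {
    acc <- n * k[r + 1]
    for (s in 1:r) {
      acc <- acc + k[r + 1 + s] * (shiftArray3d(n, s, axis, 0) +
                                     shiftArray3d(n, -s, axis, 0))
    }
    n <- acc
  }
  as.numeric(n) * (sigma / sum(k^2))
}

# Branched random-walk tube mask.
makeTubeMask <- function(p) {
  Z <- p$shape[1]; Y <- p$shape[2]; X <- p$shape[3]
  dims <- c(Y, X, Z)
  tube <- array(FALSE, dim = dims)
  rXy <- p$tubeRadiusXy; rZ <- p$tubeRadiusZ
  disc <- expand.grid(dy = -rXy:rXy, dx = -rXy:rXy, dz = -rZ:rZ)
  disc <- disc[(disc$dx^2 + disc$dy^2) / rXy^2 +
                 disc$dz^2 / max(rZ, 0.5)^2 <= 1, ]
  margin <- 6
  for (b in seq_len(p$nBranches)) {
    x <- stats::runif(1, margin, X - margin)
    y <- stats::runif(1, margin, Y - margin)
    zc <- stats::runif(1, 2, Z - 3)
    ang <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(p$branchSteps)) {
      ang <- ang + stats::rnorm(1, 0, 0.15)
      x <- x + cos(ang); y <- y + sin(ang)
      zc <- min(max(zc + stats::rnorm(1, 0, 0.05), 1.2), Z - 2.2)
      if (x < margin || x > X - margin) { ang <- pi - ang; x <- min(max(x, margin), X - margin) }
      if (y < margin || y > Y - margin) { ang <- -ang; y <- min(max(y, margin), Y - margin) }
      gx <- round(x) + disc$dx; gy <- round(y) + disc$dy
      gz <- round(zc) + disc$dz
      inb <- gx >= 0 & gx < X & gy >= 0 & gy < Y & gz >= 0 & gz < Z
      tube[coordToLinear(dims, gx[inb], gy[inb], gz[inb])] <- TRUE
    }
  }
  tube
}

# Is any mask voxel within the centered reach box of a coordinate?
nearMask <- function(mask, coord, reachXy, reachZ = 1) {
  dims <- dim(mask)
  xr <- max(0, coord[1] - reachXy):min(dims[2] - 1, coord[1] + reachXy)
  yr <- max(0, coord[2] - reachXy):min(dims[1] - 1, coord[2] + reachXy)
  zr <- max(0, coord[3] - reachZ):min(dims[3] - 1, coord[3] + reachZ)
  any(mask[yr + 1, xr + 1, zr + 1])
}

#' Sample labeled training ROIs from a synthetic scene
#'
#' Positives are ROIs centered on randomly chosen true synapse centers.
#' Negatives are drawn from three realistic distractor pools: planted
#' artifact centers (up to 20\% of the negatives), foreground-adjacent ring
#' positions 3-6 xy voxels from a synapse center, and bright background spots
#' (a random voxel replaced by the brightest voxel in its 5 x 5 x 3
#' neighborhood, emulating the distractor-like spots an annotator would tag).
#' Every negative lies at least 3 xy voxels from every true center.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param volume the scene's synapse-channel \linkS4class{VolumeStack}.
#' @param nPos,nNeg numbers of positive / negative ROIs (default 25 + 25).
#' @param seed RNG seed.
#' @param roiSize ROI extent \code{(w, h, d)}.
#' @return List of labeled \linkS4class{Roi3D} (positives first).
#' @export
sampleTrainingRois <- function(scene, volume, nPos = 25, nNeg = 25, seed = 1,
                               roiSize = c(9, 9, 3)) {
  stopifnot(is(scene, "SyntheticScene"), is(volume, "VolumeStack"))
  tc <- markerCoords(scene@trueCenters)
  if (nrow(tc) < nPos)
    stop(sprintf("scene has %d true centers, %d positives requested",
                 nrow(tc), nPos), call. = FALSE)
  d <- dim(volume@data)
  a <- stackData(volume)
  minXy <- function(cand) {
    min(sqrt((tc[, 1] - cand[1])^2 + (tc[, 2] - cand[2])^2))
  }
  withSeed(seed, {
    pos <- tc[sample(nrow(tc), nPos), , drop = FALSE]
    neg <- matrix(numeric(0), 0, 3)
    push <- function(cand) {
      if (cand[1] < 0 || cand[1] >= d[2] || cand[2] < 0 || cand[2] >= d[1] ||
          cand[3] < 0 || cand[3] >= d[3]) return(FALSE)
      if (minXy(cand) < 3) return(FALSE)
      if (nrow(neg) && any(neg[, 1] == cand[1] & neg[, 2] == cand[2] &
                             neg[, 3] == cand[3])) return(FALSE)
      neg <<- rbind(neg, cand)
      TRUE
    }
    ac <- markerCoords(scene@artifactCenters)
    nArt <- min(nrow(ac), floor(nNeg * 0.2))
    if (nArt > 0) for (i in sample(nrow(ac), nArt)) push(ac[i, ])
    nRing <- floor((nNeg - nrow(neg)) / 2)
    tries <- 0
    while (nrow(neg) < nArt + nRing && tries < 20000) {
      tries <- tries + 1
      ct <- tc[sample(nrow(tc), 1), ]
      r <- stats::runif(1, 3.2, 6); th <- stats::runif(1, 0, 2 * pi)
      push(c(round(ct[1] + r * cos(th)), round(ct[2] + r * sin(th)), ct[3]))
    }
    tries <- 0
    while (nrow(neg) < nNeg && tries < 20000) {
      tries <- tries + 1
      cand <- c(sample(0:(d[2] - 1), 1), sample(0:(d[1] - 1), 1),
                sample(0:(d[3] - 1), 1))
      # snap to the brightest voxel of the local window
      xr <- max(0, cand[1] - 2):min(d[2] - 1, cand[1] + 2)
      yr <- max(0, cand[2] - 2):min(d[1] - 1, cand[2] + 2)
      zr <- max(0, cand[3] - 1):min(d[3] - 1, cand[3] + 1)
      w <- a[yr + 1, xr + 1, zr + 1, drop = FALSE]
      am <- which.max(w)
      co <- arrayInd(am, dim(w))
      push(c(xr[co[2]], yr[co[1]], zr[co[3]]))
    }
    if (nrow(neg) < nNeg)
      stop("could not sample enough negatives", call. = FALSE)
    c(lapply(seq_len(nPos), function(i)
        extractRoi(volume, pos[i, ], roiSize, label = "positive")),
      lapply(seq_len(nrow(neg)), function(i)
        extractRoi(volume, neg[i, ], roiSize, label = "negative")))
  })
}

#' @describeIn SyntheticScene-class true synapse centers.
#' @param object a \code{SyntheticScene}.
#' @export
setGeneric("trueCenters", function(object) standardGeneric("trueCenters"))

#' @export
setMethod("trueCenters", "SyntheticScene", function(object) object@trueCenters)

#' @describeIn SyntheticScene-class planted artifact centers.
#' @export
setGeneric("artifactCenters", function(object) standardGeneric("artifactCenters"))

#' @export
setMethod("artifactCenters", "SyntheticScene",
          function(object) object@artifactCenters)

#' @describeIn SyntheticScene-class logical tube mask.
#' @export
setGeneric("morphologyMask", function(object) standardGeneric("morphologyMask"))

#' @export
setMethod("morphologyMask", "SyntheticScene",
          function(object) object@morphologyMask)

#' @describeIn SyntheticScene-class ground-truth per-voxel labels.
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))

#' @export
setMethod("trueLabels", "SyntheticScene", function(object) object@trueLabels)
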