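# Candidate generation and model-based synapse center detection.
#
# Candidates are masked 3D local maxima (default 7 x 7 x 5 search locality)
# of the synapse channel over the RATS over-mask; each candidate's ROI is
# classified by the trained model, positives are refined by iterative mean
# shift to the nearby center of mass, and near-duplicate centers are merged.

#' Detection parameters
#'
#' @param maximaNeighborhood local-maxima search locality \code{(x, y, z)},
#'   all odd (default \code{c(7, 7, 5)}).
#' @param roiSize classification ROI \code{(w, h, d)} (default
#'   \code{c(9, 9, 3)}).
#' @param shiftWindow mean-shift window (default \code{c(9, 9, 3)}).
#' @param shiftTol convergence tolerance in voxels (default 0.5).
#' @param shiftMaxIter maximum mean-shift iterations (default 20).
#' @param expectedSizeXy expected synapse diameter in xy voxels (default 7).
#' @param mergeFraction two centers closer than
#'   \code{mergeFraction * expectedSizeXy} (anisotropy-scaled voxels) are
#'   merged (default 0.5).
#' @return A validated named list.
#' @export
detectionParams <- function(maximaNeighborhood = c(7, 7, 5),
                            roiSize = c(9, 9, 3),
                            shiftWindow = c(9, 9, 3), shiftTol = 0.5,
                            shiftMaxIter = 20, expectedSizeXy = 7,
                            mergeFraction = 0.5) {
  stopIfNotOdd(maximaNeighborhood, "maximaNeighborhood")
  stopIfNotOdd(roiSize, "roiSize")
  stopIfNotOdd(shiftWindow, "shiftWindow")
  stopifnot(shiftTol > 0, shiftMaxIter >= 1, expectedSizeXy > 0,
            mergeFraction > 0, mergeFraction <= 1)
  list(maximaNeighborhood = as.integer(maximaNeighborhood),
       roiSize = as.integer(roiSize), shiftWindow = as.integer(shiftWindow),
       shiftTol = shiftTol, shiftMaxIter = as.integer(shiftMaxIter),
       expectedSizeXy = expectedSizeXy, mergeFraction = mergeFraction)
}

#' Masked 3D local maxima
#'
#' A voxel is a candidate iff it is foreground in \code{mask} and its
#' intensity equals the maximum over the centered \code{neighborhood} box
#' (clipped at the volume border). Within a 26-connected plateau of equal
#' candidate maxima only the voxel with the smallest \code{(z, y, x)} is kept.
#'
#' @param volume a \linkS4class{VolumeStack}.
#' @param mask logical array of the same shape (e.g. a RATS over-mask).
#' @param neighborhood search locality \code{(x, y, z)}, all odd.
#' @return A \linkS4class{MarkerSet} with status \code{raw} and the voxel
#'   intensity as score, ordered by \code{(z, y, x)}.
#' @export
localMaxima <- function(volume, mask, neighborhood = c(7, 7, 5)) {
  stopifnot(is(volume, "VolumeStack"))
  stopIfNotOdd(neighborhood, "neighborhood")
  a <- stackData(volume)
  if (!identical(dim(mask), dim(a)))
    stop("mask shape does not match volume", call. = FALSE)
  bm <- boxMax3d(a, as.integer(neighborhood))
  cand <- which(mask & (a == bm))
  if (!length(cand)) return(MarkerSet())
  co <- linearToCoord(dim(a), cand)
  vals <- a[cand]
  keep <- dedupePlateaus(dim(a), cand, co, vals)
  co <- co[keep, , drop = FALSE]
  ord <- order(co[, "z"], co[, "y"], co[, "x"])
  co <- co[ord, , drop = FALSE]
  MarkerSet(x = co[, "x"], y = co[, "y"], z = co[, "z"],
            score = vals[keep][ord], status = "raw")
}

# Among candidate voxels, group 26-connected equal-valued plateaus and keep
# the smallest (z, y, x) member of each.
dedupePlateaus <- function(dims, cand, co, vals) {
  n <- length(cand)
  rank <- integer(prod(dims))
  rank[cand] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  for (k in seq_len(nrow(offs))) {
    nx <- co[, "x"] + offs$dx[k]; ny <- co[, "y"] + offs$dy[k]
    nz <- co[, "z"] + offs$dz[k]
    ok <- nx >= 0 & nx < dims[2] & ny >= 0 & ny < dims[1] &
          nz >= 0 & nz < dims[3]
    if (!any(ok)) next
    nidx <- coordToLinear(dims, nx[ok], ny[ok], nz[ok])
    nr <- rank[nidx]
    src <- which(ok)[nr > 0]
    dst <- nr[nr > 0]
    eq <- vals[src] == vals[dst]
    for (e in which(eq)) {
      a <- find(src[e]); b <- find(dst[e])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ordKey <- order(co[, "z"], co[, "y"], co[, "x"])
  first <- !duplicated(comp[ordKey])
  sort(ordKey[first])
}

#' Classify candidate centers with a trained model
#'
#' Extracts the ROI around each candidate, computes the chain's features and
#' keeps candidates the model predicts positive; kept markers carry the model
#' score and gain status \code{classified}.
#'
#' @param model an \linkS4class{MlpModel} (its stored chain supplies the
#'   extractors; a bare model defaults to the anisotropic Haar extractor).
#' @param volume the synapse-channel \linkS4class{VolumeStack}.
#' @param candidates a \linkS4class{MarkerSet}.
#' @param roiSize ROI extent, matching the training ROI size.
#' @return The retained \linkS4class{MarkerSet}.
#' @export
classifyCandidates <- function(model, volume, candidates,
                               roiSize = c(9, 9, 3)) {
  stopifnot(is(candidates, "MarkerSet"))
  m <- markers(candidates)
  if (!nrow(m)) return(candidates)
  extractors <- chainExtractors(model)
  rois <- lapply(seq_len(nrow(m)), function(i)
    extractRoi(volume, c(m$x[i], m$y[i], m$z[i]), roiSize))
  X <- featureMatrix(rois, extractors)
  pr <- if (is(model, "MlpModel")) predict(model, X)
        else data.frame(score = classifierScores(model, X)) |>
             transform(label = ifelse(score > 0.5, "positive", "negative"))
  keep <- pr$label == "positive"
  out <- m[keep, , drop = FALSE]
  out$score <- pr$score[keep]
  out$status <- addStatus(out$status, "classified")
  MarkerSet(out)
}

chainExtractors <- function(model) {
  ch <- if (is(model, "MlpModel")) model@chain else NULL
  if (!is.null(ch) && length(ch$extractors)) ch$extractors
  else list(list(id = "haar3d", config = NULL))
}

#' Mean-shift refinement of a marker position
#'
#' Iteratively moves the position to the intensity-weighted centroid of the
#' window centered on the current (rounded) position, until the displacement
#' drops below \code{tol} voxels or \code{maxIter} is reached. Windows are
#' mirror-padded at the volume border. The final coordinate is rounded to the
#' nearest voxel.
#'
#' @param volume a \linkS4class{VolumeStack}.
#' @param marker 0-based \code{(x, y, z)} starting voxel.
#' @param window window extent \code{(w, h, d)}, all odd.
#' @param tol convergence tolerance in voxels.
#' @param maxIter maximum iterations.
#' @return Integer \code{(x, y, z)} of the refined position.
#' @export
meanShiftRefine <- function(volume, marker, window = c(9, 9, 3), tol = 0.5,
                            maxIter = 20) {
  stopIfNotOdd(window, "window")
  d <- dim(volume@data)
  h <- (window - 1) / 2
  ox <- -h[1]:h[1]; oy <- -h[2]:h[2]; oz <- -h[3]:h[3]
  og <- expand.grid(oy = oy, ox = ox, oz = oz)  # matches array unrolling
  pos <- as.numeric(marker)
  for (it in seq_len(maxIter)) {
    c0 <- round(pos)
    c0 <- pmin(pmax(c0, 0), c(d[2], d[1], d[3]) - 1)
    w <- roiData(extractRoi(volume, c0, window))
    tw <- sum(w)
    if (tw == 0) break
    newPos <- c0 + c(sum(w * og$ox), sum(w * og$oy), sum(w * og$oz)) / tw
    disp <- sqrt(sum((newPos - pos)^2))
    pos <- newPos
    if (disp < tol) break
  }
  out <- round(pos)
  pmin(pmax(out, 0), c(d[2], d[1], d[3]) - 1)
}

#' Mean-shift refine every marker of a set
#'
#' @param volume a \linkS4class{VolumeStack}.
#' @param markerSet a \linkS4class{MarkerSet}.
#' @param params a \code{\link{detectionParams}} list.
#' @return The refined \linkS4class{MarkerSet} (status gains \code{shifted}).
#' @export
refineMarkers <- function(volume, markerSet, params = detectionParams()) {
  m <- markers(markerSet)
  if (!nrow(m)) return(markerSet)
  for (i in seq_len(nrow(m))) {
    p <- meanShiftRefine(volume, c(m$x[i], m$y[i], m$z[i]),
                         params$shiftWindow, params$shiftTol,
                         params$shiftMaxIter)
    m$x[i] <- p[1]; m$y[i] <- p[2]; m$z[i] <- p[3]
  }
  m$status <- addStatus(m$status, "shifted")
  MarkerSet(m)
}

#' Merge mutually close markers
#'
#' Repeatedly merges the globally closest pair of markers whose
#' anisotropy-scaled Euclidean distance (z differences scaled by dz/dx) is
#' below \code{minSep}, replacing the pair by its score-weighted centroid,
#' until all surviving markers are at least \code{minSep} apart. Distance ties
#' are broken by the smallest \code{(z, y, x)} of the pair members, which
#' makes the procedure order-independent.
#'
#' @param markerSet a \linkS4class{MarkerSet}.
#' @param minSep merge radius in (anisotropy-scaled) voxels; defaults to
#'   \code{mergeFraction * expectedSizeXy} of \code{params}.
#' @param voxelSize \code{(dx, dy, dz)} used for the z scaling.
#' @param params a \code{\link{detectionParams}} list.
#' @return The merged \linkS4class{MarkerSet}; markers that took part in a
#'   merge gain status \code{merged}.
#' @export
mergeClose <- function(markerSet, minSep = NULL,
                       voxelSize = c(80, 80, 400),
                       params = detectionParams()) {
  minSep <- minSep %||% (params$mergeFraction * params$expectedSizeXy)
  stopifnot(minSep > 0)
  m <- markers(markerSet)
  if (nrow(m) < 2) return(markerSet)
  pos <- as.matrix(m[, c("x", "y", "z")])
  storage.mode(pos) <- "double"
  sc <- ifelse(is.na(m$score), 1, m$score)
  st <- m$status
  repeat {
    n <- nrow(pos)
    if (n < 2) break
    D <- scaledDistMat(pos, pos, voxelSize)
    diag(D) <- Inf
    if (min(D) >= minSep) break
    idx <- which(D == min(D), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    # tie-break: smallest (z, y, x) of the first member, then of the second
    key <- cbind(pos[idx[, 1], 3], pos[idx[, 1], 2], pos[idx[, 1], 1],
                 pos[idx[, 2], 3], pos[idx[, 2], 2], pos[idx[, 2], 1])
    pick <- do.call(order, as.data.frame(key))[1]
    i <- idx[pick, 1]; j <- idx[pick, 2]
    wsum <- sc[i] + sc[j]
    newPos <- if (wsum > 0) (sc[i] * pos[i, ] + sc[j] * pos[j, ]) / wsum
              else (pos[i, ] + pos[j, ]) / 2
    newSc <- max(sc[i], sc[j])
    newSt <- addStatus(st[i], "merged")
    pos <- rbind(pos[-c(i, j), , drop = FALSE], newPos)
    sc <- c(sc[-c(i, j)], newSc)
    st <- c(st[-c(i, j)], newSt)
  }
  pos <- round(pos)
  dup <- duplicated(pos)
  out <- MarkerSet(x = pos[!dup, 1], y = pos[!dup, 2], z = pos[!dup, 3],
                   score = sc[!dup], status = st[!dup])
  m2 <- markers(out)
  ord <- order(m2$z, m2$y, m2$x)
  MarkerSet(m2[ord, , drop = FALSE])
}
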