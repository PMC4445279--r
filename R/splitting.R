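# Marker-guided splitting of synapse clumps.
#
# Clumps (connected foreground components containing more than one detected
# center) are split on their xy maximum-intensity projection: the clump
# contour is traced, each contour point gets a concavity score
#     C(i) = w_{i-1} + w_i + w_{i+1}
# (w = foreground count in the 5x5 window at the point), and the cut is the
# chord {i, j} maximizing the split energy
#     E({i, j}) = C(i) * C(j) / d(i, j)
# among chords that place the target marker on its own side. Splitting
# recurses, peeling off the marker with maximal sum distance to the rest,
# until each child holds exactly one marker; voxels follow the side of their
# xy projection pixel.

#' 26-connected components of a 3D mask
#'
#' Labels the foreground of a binary grid with 26-neighborhood connectivity
#' (face, edge and corner contacts all connect), discards objects smaller
#' than \code{minSize} voxels as noise, and renumbers the survivors by
#' decreasing size (ties by smallest bounding-box origin in \code{(z, y, x)}
#' order).
#'
#' @param mask logical (or 0/1) 3D array \code{[y, x, z]}.
#' @param minSize minimum object size in voxels (default 8).
#' @param voxelSize \code{(dx, dy, dz)} in nm, stored for downstream stages.
#' @return A \linkS4class{LabeledObjects}; its \code{stats} table has one row
#'   per object: label, voxel_count, centroid \code{(cx, cy, cz)} and
#'   bounding box (all 0-based).
#' @export
connectedComponents26 <- function(mask, minSize = 8,
                                  voxelSize = c(80, 80, 400)) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3)
  fg <- which(mask != 0)
  labels <- array(0L, dim = dims)
  if (!length(fg)) {
    return(new("LabeledObjects", labels = labels, stats = emptyObjectStats(),
               voxelSize = voxelSize))
  }
  rank <- integer(prod(dims))
  rank[fg] <- seq_along(fg)
  co <- linearToCoord(dims, fg)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 |
            (offs$dy == 0 & offs$dx > 0))), ]  # 13 half-neighborhood offsets
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nx <- co[, "x"] + offs$dx[k]; ny <- co[, "y"] + offs$dy[k]
    nz <- co[, "z"] + offs$dz[k]
    ok <- nx >= 0 & nx < dims[2] & ny >= 0 & ny < dims[1] &
          nz >= 0 & nz < dims[3]
    if (!any(ok)) next
    nr <- rank[coordToLinear(dims, nx[ok], ny[ok], nz[ok])]
    hit <- nr > 0
    edges[[k]] <- cbind(which(ok)[hit], nr[hit])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(el) && nrow(el)) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)$membership

  sizes <- tabulate(comp)
  keep <- which(sizes >= minSize)
  if (!length(keep)) {
    return(new("LabeledObjects", labels = labels, stats = emptyObjectStats(),
               voxelSize = voxelSize))
  }
  # bbox origin per component for tie-breaking, order (z0, y0, x0)
  x0 <- tapply(co[, "x"], comp, min)[as.character(keep)]
  y0 <- tapply(co[, "y"], comp, min)[as.character(keep)]
  z0 <- tapply(co[, "z"], comp, min)[as.character(keep)]
  ord <- order(-sizes[keep], z0, y0, x0)
  keep <- keep[ord]
  newLab <- integer(length(sizes))
  newLab[keep] <- seq_along(keep)
  lab <- newLab[comp]
  sel <- lab > 0
  labels[fg[sel]] <- lab[sel]
  new("LabeledObjects", labels = labels,
      stats = computeObjectStats(labels, co[sel, , drop = FALSE], lab[sel]),
      voxelSize = voxelSize)
}

emptyObjectStats <- function() {
  data.frame(label = integer(), voxel_count = integer(), cx = numeric(),
             cy = numeric(), cz = numeric(), x0 = integer(), y0 = integer(),
             z0 = integer(), x1 = integer(), y1 = integer(), z1 = integer(),
             marker_id = integer(), unsplittable = logical(),
             from_split = logical())
}

computeObjectStats <- function(labels, co, lab,
                               marker_id = NA_integer_,
                               unsplittable = FALSE) {
  agg <- function(v, f) as.numeric(tapply(v, lab, f))
  labs <- sort(unique(lab))
  data.frame(label = labs,
             voxel_count = as.integer(tabulate(lab)[labs]),
             cx = agg(co[, "x"], mean), cy = agg(co[, "y"], mean),
             cz = agg(co[, "z"], mean),
             x0 = as.integer(agg(co[, "x"], min)),
             y0 = as.integer(agg(co[, "y"], min)),
             z0 = as.integer(agg(co[, "z"], min)),
             x1 = as.integer(agg(co[, "x"], max)),
             y1 = as.integer(agg(co[, "y"], max)),
             z1 = as.integer(agg(co[, "z"], max)),
             marker_id = rep_len(marker_id, length(labs)),
             unsplittable = rep_len(unsplittable, length(labs)),
             from_split = rep_len(FALSE, length(labs)))
}

#' Maximum intensity projection footprint of an object
#'
#' Projects an object's voxels onto the xy plane: a pixel is foreground iff
#' the object occupies any voxel in that z column. Column membership is
#' retained so 3D voxels can later be reassigned from a 2D split.
#'
#' @param voxels matrix or data.frame of object voxel coordinates with
#'   columns \code{x, y, z} (0-based).
#' @return List with \code{mask} (logical matrix over the object's xy
#'   bounding box), \code{origin} (0-based \code{(x0, y0)} of the box) and
#'   \code{pixelOf} (index of each input voxel's projection pixel).
#' @export
mipProject <- function(voxels) {
  voxels <- as.data.frame(voxels)
  if (!nrow(voxels)) stop("empty object", call. = FALSE)
  x0 <- min(voxels$x); y0 <- min(voxels$y)
  w <- max(voxels$x) - x0 + 1L; h <- max(voxels$y) - y0 + 1L
  mask <- matrix(FALSE, h, w)
  px <- voxels$x - x0 + 1L; py <- voxels$y - y0 + 1L
  idx <- cbind(py, px)
  mask[idx] <- TRUE
  list(mask = mask, origin = c(x0 = x0, y0 = y0),
       pixelOf = (px - 1L) * h + py)
}

#' Trace the contour of a 2D object and score concavity
#'
#' Moore-neighbor boundary tracing, clockwise, starting at the topmost then
#' leftmost foreground pixel, producing a closed ordered boundary. Each
#' contour point is annotated with \code{w}, the number of foreground pixels
#' in the 5x5 window centered on it (windows are clipped at the image border;
#' out-of-image counts as background), and the concavity score
#' \code{C(i) = w[i-1] + w[i] + w[i+1]} with cyclic indices. High \code{C}
#' marks inward notches -- the natural cut anchors between fused puncta.
#'
#' @param mask logical matrix containing one 8-connected foreground object.
#' @return data.frame with columns \code{index, x, y, w, C} (\code{x, y}
#'   0-based within \code{mask}).
#' @export
traceContour <- function(mask) {
  if (!any(mask)) stop("empty object", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  fgidx <- which(mask)
  ys <- (fgidx - 1) %% h; xs <- (fgidx - 1) %/% h
  top <- min(ys)
  sx <- min(xs[ys == top]); sy <- top  # topmost, then leftmost
  isFg <- function(x, y) x >= 0 && x < w && y >= 0 && y < h && mask[y + 1, x + 1]
  # clockwise Moore neighborhood: E SE S SW W NW N NE
  DX <- c(1, 1, 0, -1, -1, -1, 0, 1)
  DY <- c(0, 1, 1, 1, 0, -1, -1, -1)
  path <- list(c(sx, sy))
  if (sum(mask) > 1) {
    p <- c(sx, sy)
    bdir <- 5L  # backtrack = west neighbor, background by start choice
    firstMove <- NULL
    maxSteps <- 8L * (sum(mask) + 2L)
    for (step in seq_len(maxSteps)) {
      hit <- 0L
      for (t in 1:8) {
        dir <- ((bdir - 1L + t) %% 8L) + 1L  # scan starts after the backtrack
        if (isFg(p[1] + DX[dir], p[2] + DY[dir])) { hit <- t; break }
      }
      if (hit == 0L) break  # isolated pixel
      # Jacob's stopping: about to repeat the initial move from the start pixel
      if (!is.null(firstMove) &&
          p[1] == sx && p[2] == sy && dir == firstMove) break
      if (is.null(firstMove)) firstMove <- dir
      prevDir <- ((bdir - 1L + hit - 1L) %% 8L) + 1L  # last background scanned
      bpos <- c(p[1] + DX[prevDir], p[2] + DY[prevDir])
      p <- c(p[1] + DX[dir], p[2] + DY[dir])
      bdir <- which(DX == bpos[1] - p[1] & DY == bpos[2] - p[2])
      path[[length(path) + 1]] <- p
    }
    # drop the closing revisit of the start pixel
    last <- path[[length(path)]]
    if (length(path) > 1 && last[1] == sx && last[2] == sy)
      path[[length(path)]] <- NULL
  }
  pts <- do.call(rbind, path)
  n <- nrow(pts)
  wv <- vapply(seq_len(n), function(i) {
    x <- pts[i, 1]; y <- pts[i, 2]
    xr <- max(0, x - 2):min(w - 1, x + 2)
    yr <- max(0, y - 2):min(h - 1, y + 2)
    sum(mask[yr + 1, xr + 1, drop = FALSE])
  }, numeric(1))
  Cv <- wv[((seq_len(n) - 2) %% n) + 1] + wv + wv[(seq_len(n) %% n) + 1]
  data.frame(index = seq_len(n), x = pts[, 1], y = pts[, 2], w = wv, C = Cv)
}

#' Split energy of a contour point pair
#'
#' \code{E = C(i) * C(j) / d(i, j)} with \code{d} the Euclidean pixel
#' distance: the cut favors mutually close, highly concave point pairs.
#'
#' @param pi,pj single rows of a \code{\link{traceContour}} data.frame (or
#'   any list with \code{x, y, C}).
#' @return List with \code{i, j, E, d}.
#' @export
splitEnergy <- function(pi, pj) {
  d <- sqrt((pi$x - pj$x)^2 + (pi$y - pj$y)^2)
  if (d == 0) stop("coincident contour points", call. = FALSE)
  list(i = pi$index %||% NA_integer_, j = pj$index %||% NA_integer_,
       E = pi$C * pj$C / d, d = d)
}

# Bresenham raster of the segment between two 0-based pixel coordinates.
bresenhamLine <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  out <- matrix(NA_integer_, dx + dy + 1, 2)
  k <- 0L
  repeat {
    k <- k + 1L
    out[k, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx) { err <- err + dx; y0 <- y0 + sy }
  }
  out[seq_len(k), , drop = FALSE]
}

# 8-connected labeling of a logical matrix (iterative flood fill).
label2d8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      py <- (p - 1L) %% h; px <- (p - 1L) %/% h
      for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0) next
        ny <- py + dy; nx <- px + dx
        if (ny < 0 || ny >= h || nx < 0 || nx >= w) next
        q <- nx * h + ny + 1L
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; stack <- c(stack, q) }
      }
    }
  }
  lab
}

#' Find the optimal separating chord for one marker
#'
#' Walks contour points \code{A} in order of decreasing concavity; for each
#' \code{A}, candidate partners \code{B} are tried in order of decreasing
#' split energy, and the first chord whose removal leaves the target marker's
#' pixel 8-disconnected from every other marker's pixel wins (so the returned
#' pair maximizes the split energy among valid pairs for that \code{A}). Ties
#' are broken by the smaller contour index of \code{B}, then of \code{A}.
#'
#' @param contour a \code{\link{traceContour}} data.frame.
#' @param mask the object's 2D projection mask.
#' @param markers2d matrix of projected marker pixels (columns \code{x, y},
#'   0-based within \code{mask}).
#' @param target row index (into \code{markers2d}) of the marker to separate.
#' @return List with \code{i, j, E, d, chord} (chord pixel matrix), or
#'   \code{NULL} when no chord separates the target ("unsplittable").
#' @export
findSplit <- function(contour, mask, markers2d, target = 1) {
  n <- nrow(contour)
  if (nrow(markers2d) < 2) stop("need at least 2 markers", call. = FALSE)
  h <- nrow(mask)
  mIdx <- markers2d[, 1] * h + markers2d[, 2] + 1L  # linear pixel indices
  aOrder <- order(-contour$C, contour$index)
  for (ai in aOrder) {
    A <- contour[ai, ]
    others <- setdiff(seq_len(n), ai)
    d <- sqrt((contour$x[others] - A$x)^2 + (contour$y[others] - A$y)^2)
    valid <- d > 0
    others <- others[valid]; d <- d[valid]
    if (!length(others)) next
    E <- A$C * contour$C[others] / d
    ob <- order(-E, contour$index[others])
    bOrder <- others[ob]; Eord <- E[ob]; dOrd <- d[ob]
    for (k in seq_along(bOrder)) {
      bi <- bOrder[k]
      chord <- bresenhamLine(A$x, A$y, contour$x[bi], contour$y[bi])
      cut <- mask
      cut[chord[, 1] * h + chord[, 2] + 1L] <- FALSE
      if (!cut[mIdx[target]]) next        # target sits on the chord
      if (any(!cut[mIdx[-target]])) next  # another marker sits on the chord
      lab <- label2d8(cut)
      lt <- lab[mIdx[target]]
      if (all(lab[mIdx[-target]] != lt)) {
        return(list(i = contour$index[ai], j = contour$index[bi],
                    E = Eord[k], d = dOrd[k], chord = chord))
      }
    }
  }
  NULL
}

#' Recursively split one clump guided by its markers
#'
#' Implements the marker-pool recursion: pick the marker M1 with maximal
#' (anisotropy-scaled) sum distance to the remaining pool, find the optimal
#' chord separating it on the xy projection, assign every voxel to the side
#' of its projection pixel (chord pixels go to the side of the nearer marker,
#' ties to M1's side), and recurse on the remainder until one marker is left.
#' When no chord separates a marker the remaining voxels stay together as a
#' single child flagged \code{unsplittable}.
#'
#' @param voxels matrix/data.frame of the clump's voxel coordinates
#'   (\code{x, y, z}, 0-based).
#' @param markerDf data.frame of guiding markers with columns
#'   \code{id, x, y, z}.
#' @param voxelSize \code{(dx, dy, dz)} in nm for the anisotropy scaling.
#' @return List of children: each has \code{voxels} (data.frame),
#'   \code{marker_id} (vector of guiding marker ids; length 1 unless
#'   unsplittable) and \code{unsplittable} flag. Children partition the
#'   input voxels exactly.
#' @export
recursiveSplit <- function(voxels, markerDf, voxelSize = c(80, 80, 400)) {
  voxels <- as.data.frame(voxels)
  markerDf <- as.data.frame(markerDf)
  if (!nrow(markerDf)) stop("object contains no markers", call. = FALSE)
  if (nrow(markerDf) == 1)
    return(list(list(voxels = voxels, marker_id = markerDf$id,
                     unsplittable = FALSE)))
  pm <- as.matrix(markerDf[, c("x", "y", "z")])
  D <- scaledDistMat(pm, pm, voxelSize)
  sums <- rowSums(D)
  ord <- order(-sums, markerDf$z, markerDf$y, markerDf$x)
  t1 <- ord[1]

  proj <- mipProject(voxels)
  mask <- proj$mask
  h <- nrow(mask)
  m2 <- cbind(markerDf$x - proj$origin["x0"], markerDf$y - proj$origin["y0"])
  m2 <- snapToMask(m2, mask)
  coincident <- any(m2[-t1, 1] == m2[t1, 1] & m2[-t1, 2] == m2[t1, 2])
  if (coincident) {
    # target coincides with another marker in projection: cannot separate
    return(list(list(voxels = voxels, marker_id = markerDf$id,
                     unsplittable = TRUE)))
  }
  contour <- traceContour(mask)
  sp <- findSplit(contour, mask, m2, target = t1)
  if (is.null(sp)) {
    return(list(list(voxels = voxels, marker_id = markerDf$id,
                     unsplittable = TRUE)))
  }
  cut <- mask
  cut[sp$chord[, 1] * h + sp$chord[, 2] + 1L] <- FALSE
  lab <- label2d8(cut)
  ltarget <- lab[m2[t1, 1] * h + m2[t1, 2] + 1L]
  # side of every foreground pixel: 1 = target, 2 = rest
  pixSide <- matrix(0L, nrow(mask), ncol(mask))
  pixSide[mask & lab == ltarget] <- 1L
  pixSide[mask & lab != ltarget & lab > 0] <- 2L
  onChord <- which(mask & lab == 0)
  if (length(onChord)) {
    cy <- (onChord - 1L) %% h; cx <- (onChord - 1L) %/% h
    dT <- sqrt((cx - m2[t1, 1])^2 + (cy - m2[t1, 2])^2)
    rest <- m2[-t1, , drop = FALSE]
    dR <- apply(cbind(cx, cy), 1, function(p)
      min(sqrt((rest[, 1] - p[1])^2 + (rest[, 2] - p[2])^2)))
    pixSide[onChord] <- ifelse(dT <= dR, 1L, 2L)
  }
  side <- pixSide[cbind(voxels$y - proj$origin["y0"] + 1L,
                        voxels$x - proj$origin["x0"] + 1L)]
  child1 <- voxels[side == 1L, , drop = FALSE]
  restVox <- voxels[side == 2L, , drop = FALSE]
  c(list(list(voxels = child1, marker_id = markerDf$id[t1],
              unsplittable = FALSE)),
    recursiveSplit(restVox, markerDf[-t1, , drop = FALSE], voxelSize))
}

# Snap projected marker pixels onto the nearest mask pixel (rounding can land
# a marker just off the object's projection).
snapToMask <- function(m2, mask) {
  h <- nrow(mask)
  fg <- which(mask)
  fy <- (fg - 1L) %% h; fx <- (fg - 1L) %/% h
  for (i in seq_len(nrow(m2))) {
    x <- m2[i, 1]; y <- m2[i, 2]
    if (x >= 0 && x < ncol(mask) && y >= 0 && y < h && mask[y + 1, x + 1])
      next
    j <- which.min((fx - x)^2 + (fy - y)^2)
    m2[i, ] <- c(fx[j], fy[j])
  }
  m2
}

#' Split all multi-marker objects of a segmentation
#'
#' Assigns each marker to the object whose label covers its voxel, runs
#' \code{\link{recursiveSplit}} on every object holding two or more markers,
#' and rebuilds the label grid with children renumbered by decreasing size.
#' Objects containing no marker are kept unchanged (their \code{marker_id}
#' is \code{NA}).
#'
#' @param objects a \linkS4class{LabeledObjects} from
#'   \code{\link{connectedComponents26}}.
#' @param markerSet the guiding \linkS4class{MarkerSet}.
#' @param voxelSize \code{(dx, dy, dz)} in nm.
#' @param maxSize objects larger than this many voxels are left intact:
#'   they exceed the plausible synapse size bound (the same 1000-voxel
#'   upper limit used by \code{\link{quantifyObjects}}), so they are
#'   background structure, not synapse clumps.
#' @return A \linkS4class{LabeledObjects} whose stats carry the guiding
#'   \code{marker_id} (row number in \code{markers(markerSet)}) and the
#'   \code{unsplittable} flag.
#' @export
splitObjects <- function(objects, markerSet,
                         voxelSize = c(80, 80, 400), maxSize = 1000) {
  stopifnot(is(objects, "LabeledObjects"), is(markerSet, "MarkerSet"))
  lab <- labelArray(objects)
  dims <- dim(lab)
  mk <- markers(markerSet)
  mlab <- if (nrow(mk)) lab[coordToLinear(dims, mk$x, mk$y, mk$z)] else integer()
  pieces <- list()
  for (L in objectStats(objects)$label) {
    idx <- which(lab == L)
    vox <- as.data.frame(linearToCoord(dims, idx))
    mids <- which(mlab == L)
    if (length(mids) < 2 || length(idx) > maxSize) {
      pieces[[length(pieces) + 1]] <-
        list(voxels = vox,
             marker_id = if (length(mids)) mids else NA_integer_,
             unsplittable = FALSE, from_split = FALSE)
    } else {
      kids <- recursiveSplit(vox, data.frame(id = mids, x = mk$x[mids],
                                             y = mk$y[mids], z = mk$z[mids]),
                             voxelSize)
      kids <- lapply(kids, function(k) {
        k$from_split <- !k$unsplittable
        k
      })
      pieces <- c(pieces, kids)
    }
  }
  rebuildLabeledObjects(pieces, dims, voxelSize)
}

rebuildLabeledObjects <- function(pieces, dims, voxelSize) {
  sizes <- vapply(pieces, function(p) nrow(p$voxels), integer(1))
  org <- t(vapply(pieces, function(p)
    c(min(p$voxels$z), min(p$voxels$y), min(p$voxels$x)), numeric(3)))
  ord <- order(-sizes, org[, 1], org[, 2], org[, 3])
  labels <- array(0L, dim = dims)
  rows <- list()
  for (newL in seq_along(ord)) {
    p <- pieces[[ord[newL]]]
    v <- p$voxels
    labels[coordToLinear(dims, v$x, v$y, v$z)] <- newL
    rows[[newL]] <- data.frame(
      label = newL, voxel_count = nrow(v),
      cx = mean(v$x), cy = mean(v$y), cz = mean(v$z),
      x0 = min(v$x), y0 = min(v$y), z0 = min(v$z),
      x1 = max(v$x), y1 = max(v$y), z1 = max(v$z),
      marker_id = p$marker_id[1], unsplittable = p$unsplittable,
      from_split = isTRUE(p$from_split))
  }
  new("LabeledObjects", labels = labels, stats = do.call(rbind, rows),
      voxelSize = voxelSize)
}

#' Summary statistics of detected objects
#'
#' Reports per-object voxel sizes and the count, minimum, maximum and mean
#' size over objects within the plausible synapse size range (default 8 to
#' 1000 voxels); the per-child centroids are the refined synapse positions.
#'
#' @param objects a \linkS4class{LabeledObjects}.
#' @param sizeRange inclusive \code{(min, max)} voxel-count bounds.
#' @return List with \code{count}, \code{sizes}, \code{min}, \code{max},
#'   \code{mean} (over in-range objects) and \code{centers} (data.frame of
#'   all object centroids with sizes).
#' @export
quantifyObjects <- function(objects, sizeRange = c(8, 1000)) {
  st <- objectStats(objects)
  sizes <- st$voxel_count
  inr <- sizes >= sizeRange[1] & sizes <= sizeRange[2]
  list(count = sum(inr),
       sizes = sizes[inr],
       min = if (any(inr)) min(sizes[inr]) else NA_real_,
       max = if (any(inr)) max(sizes[inr]) else NA_real_,
       mean = if (any(inr)) mean(sizes[inr]) else NA_real_,
       centers = data.frame(label = st$label, x = st$cx, y = st$cy,
                            z = st$cz, voxel_count = sizes))
}
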