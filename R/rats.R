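# Robust Adaptive Threshold Selection (RATS).
#
# Per slice, the image is divided into a quadtree of regions; each region gets
# the gradient-weighted intensity threshold
#     T = sum(G^2 * I) / sum(G^2)
# where G is the Sobel gradient magnitude. Regions whose gradient mass does
# not exceed a noise floor defer to their parent; leaflet thresholds are then
# bilinearly interpolated across the slice. The stack is processed slice by
# slice ("pseudo-3D") with one shared parameter set.

#' RATS parameters
#'
#' @param leafletSize edge length (pixels) of the smallest quadtree region
#'   below which no further split occurs; must be >= 2.
#' @param minNoise noise-amplitude estimate in intensity units; regions whose
#'   squared-gradient mass does not exceed
#'   \code{(scalingFactor * minNoise)^2} per gradient-bearing pixel are
#'   considered too flat to threshold and inherit their parent's threshold.
#' @param scalingFactor dimensionless multiplier on \code{minNoise} in the
#'   validity test (> 0).
#' @param minDepth quadtree depth built where the image size permits
#'   (default 5 levels, root = level 1).
#' @return A named list of validated parameters.
#' @export
ratsParams <- function(leafletSize = 16, minNoise = 10, scalingFactor = 3,
                       minDepth = 5) {
  stopifnot(leafletSize >= 2, minNoise >= 0, scalingFactor > 0, minDepth >= 1)
  list(leafletSize = as.integer(leafletSize), minNoise = minNoise,
       scalingFactor = scalingFactor, minDepth = as.integer(minDepth))
}

#' Permissive variant of a RATS parameter set
#'
#' The foreground mask that supports local-maxima detection must contain every
#' true peak (an "over-mask"), so its noise floor is halved relative to the
#' nominal segmentation parameters.
#'
#' @param params a \code{\link{ratsParams}} list.
#' @return The same parameters with \code{minNoise} halved.
#' @export
overmaskParams <- function(params) {
  params$minNoise <- params$minNoise / 2
  params
}

#' Sobel gradient magnitude of a slice
#'
#' 3x3 horizontal and vertical Sobel kernels with mirror border extension;
#' returns \code{sqrt(gx^2 + gy^2)} per pixel.
#'
#' @param slice numeric matrix \code{[y, x]}, at least 3 x 3.
#' @return numeric matrix of gradient magnitudes, same size as \code{slice}.
#' @export
sobelGradient <- function(slice) {
  d <- dim(slice)
  if (is.null(d) || any(d < 3)) stop("slice must be at least 3 x 3",
                                     call. = FALSE)
  ys <- mirrorIdx(-1:(d[1]), d[1]) + 1L
  xs <- mirrorIdx(-1:(d[2]), d[2]) + 1L
  p <- slice[ys, xs]  # padded by 1 on each side
  i <- 2:(d[1] + 1); j <- 2:(d[2] + 1)
  gx <- (p[i - 1, j + 1] + 2 * p[i, j + 1] + p[i + 1, j + 1]) -
        (p[i - 1, j - 1] + 2 * p[i, j - 1] + p[i + 1, j - 1])
  gy <- (p[i + 1, j - 1] + 2 * p[i + 1, j] + p[i + 1, j + 1]) -
        (p[i - 1, j - 1] + 2 * p[i - 1, j] + p[i - 1, j + 1])
  sqrt(gx^2 + gy^2)
}

#' Gradient-weighted regional threshold
#'
#' Computes \code{T = sum(G^2 * I) / sum(G^2)} over a region. The region is
#' valid only if its squared-gradient mass exceeds
#' \code{(scalingFactor * minNoise)^2} per gradient-bearing pixel; otherwise
#' \code{NA} is returned and the caller falls back to the parent region.
#'
#' @param I numeric matrix of region intensities.
#' @param G numeric matrix of gradient magnitudes, same shape as \code{I}.
#' @param params a \code{\link{ratsParams}} list.
#' @return The threshold, or \code{NA_real_} if the region is invalid.
#' @export
leafletThreshold <- function(I, G, params = ratsParams()) {
  if (!identical(dim(I), dim(G)))
    stop("I and G must have the same shape", call. = FALSE)
  g2 <- G^2
  sg2 <- sum(g2)
  nEdge <- sum(G > 0)
  if (sg2 <= (params$scalingFactor * params$minNoise)^2 * nEdge || sg2 == 0)
    return(NA_real_)
  sum(g2 * I) / sg2
}

# Summed-area table with a zero first row/column; region sums in O(1).
satBuild <- function(m) {
  s <- rbind(0, cbind(0, m))
  t(apply(apply(s, 2, cumsum), 1, cumsum))
}
satSum <- function(S, y0, y1, x0, x1) {  # half-open 0-based bounds
  S[y1 + 1, x1 + 1] - S[y0 + 1, x1 + 1] - S[y1 + 1, x0 + 1] + S[y0 + 1, x0 + 1]
}

#' Build the interpolated RATS threshold field for one slice
#'
#' The quadtree is split top-down at integer midpoints (odd sizes give the
#' larger first half) until \code{minDepth} is reached or a region edge would
#' fall below \code{leafletSize}. Each region's threshold comes from
#' \code{\link{leafletThreshold}}; invalid regions inherit the nearest valid
#' ancestor, and the root falls back to the global gradient-weighted formula
#' over the whole slice, or the slice median when the slice has no gradient at
#' all. Leaflet thresholds are anchored at region centers and bilinearly
#' interpolated to every pixel (clamped beyond the outermost centers).
#'
#' @param slice numeric matrix \code{[y, x]}.
#' @param params a \code{\link{ratsParams}} list.
#' @return A \linkS4class{ThresholdField}.
#' @export
buildThresholdField <- function(slice, params = ratsParams()) {
  G <- sobelGradient(slice)
  g2 <- G^2
  Sg2 <- satBuild(g2)
  Swi <- satBuild(g2 * slice)
  Sne <- satBuild((G > 0) * 1)
  H <- nrow(slice); W <- ncol(slice)
  lim2 <- (params$scalingFactor * params$minNoise)^2

  regionT <- function(y0, y1, x0, x1) {
    sg2 <- satSum(Sg2, y0, y1, x0, x1)
    ne <- satSum(Sne, y0, y1, x0, x1)
    if (sg2 <= lim2 * ne || sg2 == 0) return(NA_real_)
    satSum(Swi, y0, y1, x0, x1) / sg2
  }

  totalG2 <- satSum(Sg2, 0, H, 0, W)
  rootFallback <- if (totalG2 > 0)
    satSum(Swi, 0, H, 0, W) / totalG2 else stats::median(slice)

  leaves <- list()
  rec <- function(y0, y1, x0, x1, depth, parentT) {
    t <- regionT(y0, y1, x0, x1)
    eff <- if (is.na(t)) parentT else t
    h <- y1 - y0; w <- x1 - x0
    if (depth < params$minDepth && h >= params$leafletSize &&
        w >= params$leafletSize && h >= 2 && w >= 2) {
      my <- y0 + ceiling(h / 2)
      mx <- x0 + ceiling(w / 2)
      rec(y0, my, x0, mx, depth + 1, eff)
      rec(y0, my, mx, x1, depth + 1, eff)
      rec(my, y1, x0, mx, depth + 1, eff)
      rec(my, y1, mx, x1, depth + 1, eff)
    } else {
      leaves[[length(leaves) + 1]] <<- c((y0 + y1 - 1) / 2, (x0 + x1 - 1) / 2,
                                         eff)
    }
    invisible(NULL)
  }
  rec(0, H, 0, W, 1, rootFallback)

  lv <- do.call(rbind, leaves)
  cy <- sort(unique(lv[, 1])); cx <- sort(unique(lv[, 2]))
  Tg <- matrix(NA_real_, length(cy), length(cx))
  Tg[cbind(match(lv[, 1], cy), match(lv[, 2], cx))] <- lv[, 3]

  field <- bilinearField(cy, cx, Tg, H, W)
  new("ThresholdField", field = field,
      leafCenters = list(y = cy, x = cx), leafThresholds = Tg,
      params = params)
}

# Bilinear interpolation of grid values Tg at centers (cy, cx) onto an
# H x W pixel grid (0-based pixel coordinates), clamped at the borders.
bilinearField <- function(cy, cx, Tg, H, W) {
  interpWeights <- function(centers, n) {
    pos <- 0:(n - 1)
    k <- length(centers)
    if (k == 1) return(list(lo = rep(1L, n), hi = rep(1L, n), w = rep(0, n)))
    j <- findInterval(pos, centers)
    lo <- pmin(pmax(j, 1L), k - 1L)
    hi <- lo + 1L
    w <- (pos - centers[lo]) / (centers[hi] - centers[lo])
    w <- pmin(pmax(w, 0), 1)
    list(lo = lo, hi = hi, w = w)
  }
  ry <- interpWeights(cy, H)
  rx <- interpWeights(cx, W)
  A <- Tg[ry$lo, , drop = FALSE] * (1 - ry$w) +
       Tg[ry$hi, , drop = FALSE] * ry$w            # H x k2
  t(t(A[, rx$lo, drop = FALSE]) * (1 - rx$w) +
    t(A[, rx$hi, drop = FALSE]) * rx$w)            # H x W
}

#' Pseudo-3D RATS foreground mask
#'
#' Applies RATS independently to every slice of the stack with one shared
#' parameter set; a pixel is foreground iff its intensity strictly exceeds its
#' interpolated threshold. The reference slice (default: the middle slice,
#' which is typically the brightest) anchors the parameter set; with
#' \code{applyReferenceField = TRUE} the reference slice's threshold field is
#' reused for all slices instead of recomputing per slice.
#'
#' @param volume a \linkS4class{VolumeStack}.
#' @param params a \code{\link{ratsParams}} list.
#' @param reference \code{"middle"} or a 0-based slice index.
#' @param applyReferenceField if \code{TRUE}, threshold every slice with the
#'   reference slice's field; default recomputes the field per slice.
#' @return A logical array \code{[y, x, z]}, \code{TRUE} = foreground.
#' @export
ratsMask <- function(volume, params = ratsParams(), reference = "middle",
                     applyReferenceField = FALSE) {
  stopifnot(is(volume, "VolumeStack"))
  a <- stackData(volume)
  Z <- dim(a)[3]
  refIdx <- if (identical(reference, "middle")) Z %/% 2 else as.integer(reference)
  if (refIdx < 0 || refIdx >= Z)
    stop(sprintf("reference slice %d out of range [0, %d]", refIdx, Z - 1),
         call. = FALSE)
  mask <- array(FALSE, dim = dim(a))
  if (applyReferenceField) {
    f <- buildThresholdField(a[, , refIdx + 1], params)@field
    for (z in seq_len(Z)) mask[, , z] <- a[, , z] > f
  } else {
    for (z in seq_len(Z)) {
      f <- buildThresholdField(a[, , z], params)@field
      mask[, , z] <- a[, , z] > f
    }
  }
  mask
}
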