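# Anisotropic 3D Haar wavelet descriptor.
#
# Each xy plane of the ROI is mirror-padded to a dyadic size and decomposed
# with the orthonormal 2D Haar transform; the per-slice coefficient vectors
# are then combined as a weighted sum across z with the middle slice weighted
# heaviest. Summing (rather than concatenating) across z matches the
# anisotropy of confocal stacks: z carries far less resolution than xy, so it
# contributes robustness, not independent detail.

#' Configuration of the anisotropic Haar extractor
#'
#' @param levels decomposition depth (default 2).
#' @param padTo dyadic xy size planes are mirror-padded to (power of two,
#'   >= the ROI xy extent; default 16 for 9 x 9 ROIs).
#' @param zWeights per-slice weights; must sum to 1, be symmetric about the
#'   middle slice, with the middle weight maximal. Default \code{(1,2,1)/4}
#'   for depth-3 ROIs.
#' @return A validated named list.
#' @export
haarConfig <- function(levels = 2, padTo = 16, zWeights = c(1, 2, 1) / 4) {
  stopifnot(levels >= 1, padTo >= 2, bitwAnd(padTo, padTo - 1L) == 0)
  if (abs(sum(zWeights) - 1) > 1e-9) stop("zWeights must sum to 1",
                                          call. = FALSE)
  if (any(abs(zWeights - rev(zWeights)) > 1e-12))
    stop("zWeights must be symmetric about the middle slice", call. = FALSE)
  mid <- (length(zWeights) + 1) / 2
  if (zWeights[ceiling(mid)] < max(zWeights) - 1e-12)
    stop("middle zWeight must be maximal", call. = FALSE)
  if (2^levels > padTo) stop("levels too deep for padTo", call. = FALSE)
  list(levels = as.integer(levels), padTo = as.integer(padTo),
       zWeights = zWeights)
}

# Mirror-pad a matrix to `to` x `to`, centered (reflection without edge
# repetition).
padMirror2d <- function(m, to) {
  d <- dim(m)
  if (any(d > to)) stop("plane larger than padTo", call. = FALSE)
  preY <- (to - d[1]) %/% 2
  preX <- (to - d[2]) %/% 2
  ys <- mirrorIdx((-preY):(to - preY - 1), d[1]) + 1L
  xs <- mirrorIdx((-preX):(to - preX - 1), d[2]) + 1L
  m[ys, xs]
}

#' Orthonormal 2D Haar decomposition
#'
#' Standard separable Haar transform (pairwise sums and differences scaled by
#' \code{1/sqrt(2)}, rows then columns, recursing on the approximation block)
#' applied \code{levels} times to a dyadic square plane. The transform is
#' orthonormal, so total coefficient energy equals total pixel energy.
#'
#' @param plane numeric square matrix with a power-of-two edge.
#' @param levels decomposition depth; \code{2^levels} must not exceed the
#'   plane edge.
#' @return Numeric vector: the transformed plane flattened column-major
#'   (approximation block in the top-left at the deepest level).
#' @export
haar2d <- function(plane, levels = 2) {
  n <- nrow(plane)
  if (is.null(dim(plane)) || ncol(plane) != n ||
      bitwAnd(n, n - 1L) != 0)
    stop("plane must be square with a power-of-two edge", call. = FALSE)
  if (2^levels > n) stop("levels too deep for plane size", call. = FALSE)
  m <- plane
  s <- n
  for (l in seq_len(levels)) {
    b <- m[1:s, 1:s, drop = FALSE]
    h <- s / 2
    odd <- seq(1, s, by = 2); evn <- odd + 1
    # rows (along x): approximation | detail
    b <- cbind(b[, odd, drop = FALSE] + b[, evn, drop = FALSE],
               b[, odd, drop = FALSE] - b[, evn, drop = FALSE]) / sqrt(2)
    # columns (along y)
    b <- rbind(b[odd, , drop = FALSE] + b[evn, , drop = FALSE],
               b[odd, , drop = FALSE] - b[evn, , drop = FALSE]) / sqrt(2)
    m[1:s, 1:s] <- b
    s <- h
  }
  as.numeric(m)
}

#' Anisotropic 3D Haar feature vector of an ROI
#'
#' Each z slice of the ROI is mirror-padded to \code{padTo} and decomposed
#' with \code{\link{haar2d}}; the feature vector is the \code{zWeights}-
#' weighted sum of the per-slice coefficient vectors, so its length equals the
#' single-slice coefficient count (\code{padTo^2}).
#'
#' @param roi a \linkS4class{Roi3D} whose depth equals
#'   \code{length(config$zWeights)}.
#' @param config a \code{\link{haarConfig}} list.
#' @return Numeric feature vector with attribute \code{extractor_id}.
#' @export
anisotropicHaar3d <- function(roi, config = haarConfig()) {
  a <- if (is(roi, "Roi3D")) roiData(roi) else roi
  d <- dim(a)
  if (d[3] != length(config$zWeights))
    stop(sprintf("ROI depth %d does not match %d z-weights", d[3],
                 length(config$zWeights)), call. = FALSE)
  out <- 0
  for (z in seq_len(d[3])) {
    out <- out + config$zWeights[z] *
      haar2d(padMirror2d(a[, , z], config$padTo), config$levels)
  }
  structure(out, extractor_id = "haar3d")
}

# --- pluggable extractor registry ------------------------------------------

.extractors <- new.env(parent = emptyenv())

#' Register or look up a feature extractor
#'
#' Extractors are functions \code{function(roi, config)} returning a numeric
#' feature vector whose length depends only on the configuration. The
#' built-ins are \code{"haar3d"} (the anisotropic Haar descriptor) and
#' \code{"mean_intensity"} (the ROI mean, a deliberately weak baseline used in
#' chain comparisons). Additional descriptors (3D edge/structure, invariant
#' moments, ...) can be plugged in under new ids.
#'
#' @param id extractor identifier.
#' @param fun extractor function \code{function(roi, config)}.
#' @return \code{registerFeatureExtractor} invisibly returns \code{id};
#'   \code{getFeatureExtractor} returns the registered function.
#' @export
registerFeatureExtractor <- function(id, fun) {
  stopifnot(is.character(id), is.function(fun))
  assign(id, fun, envir = .extractors)
  invisible(id)
}

#' @rdname registerFeatureExtractor
#' @export
getFeatureExtractor <- function(id) {
  if (!exists(id, envir = .extractors))
    stop("unknown feature extractor: ", id, call. = FALSE)
  get(id, envir = .extractors)
}

.onLoad <- function(libname, pkgname) {
  registerFeatureExtractor("haar3d",
    function(roi, config = NULL)
      anisotropicHaar3d(roi, config %||% haarConfig()))
  registerFeatureExtractor("mean_intensity",
    function(roi, config = NULL) {
      a <- if (is(roi, "Roi3D")) roiData(roi) else roi
      structure(mean(a), extractor_id = "mean_intensity")
    })
}

# Feature matrix (rows = ROIs) for a list of extractor specs
# list(list(id=, config=), ...); multiple extractors are concatenated.
featureMatrix <- function(rois, extractors) {
  feats <- lapply(rois, function(r) {
    unlist(lapply(extractors, function(ex)
      as.numeric(getFeatureExtractor(ex$id)(r, ex$config))))
  })
  do.call(rbind, feats)
}
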