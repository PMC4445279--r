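# Precision / recall / F-measure scoring of detections against references.
#
# A detection is correct if it lies within a centered proximity box (default
# 7 x 7 x 5) of a reference center; matching is one-to-one, greedily pairing
# the globally closest (anisotropy-scaled) pairs first so no reference is
# counted twice.

#' One-to-one proximity matching of detected vs reference markers
#'
#' Candidate pairs must satisfy \code{|dx| <= (bx-1)/2}, \code{|dy| <=
#' (by-1)/2}, \code{|dz| <= (bz-1)/2}; among candidates the globally closest
#' pair (Euclidean, z scaled by dz/dx) is matched first, ties broken by the
#' smallest \code{(z, y, x)} of the detected marker.
#'
#' @param detected,reference \linkS4class{MarkerSet}s (or data.frames with
#'   \code{x, y, z}).
#' @param box proximity box \code{(x, y, z)}, all odd (default
#'   \code{c(7, 7, 5)}).
#' @param voxelSize \code{(dx, dy, dz)} in nm for the distance scaling.
#' @return data.frame with columns \code{det, ref} (row indices) and
#'   \code{dist}; zero rows when nothing matches.
#' @export
matchMarkers <- function(detected, reference, box = c(7, 7, 5),
                         voxelSize = c(80, 80, 400)) {
  stopIfNotOdd(box, "box")
  d <- asCoordDf(detected); r <- asCoordDf(reference)
  hb <- (box - 1) / 2
  empty <- data.frame(det = integer(), ref = integer(), dist = numeric())
  if (!nrow(d) || !nrow(r)) return(empty)
  dm <- as.matrix(d[, c("x", "y", "z")])
  rm_ <- as.matrix(r[, c("x", "y", "z")])
  ok <- abs(outer(dm[, 1], rm_[, 1], "-")) <= hb[1] &
        abs(outer(dm[, 2], rm_[, 2], "-")) <= hb[2] &
        abs(outer(dm[, 3], rm_[, 3], "-")) <= hb[3]
  if (!any(ok)) return(empty)
  D <- scaledDistMat(dm, rm_, voxelSize)
  D[!ok] <- Inf
  pairs <- which(is.finite(D), arr.ind = TRUE)
  o <- order(D[pairs], dm[pairs[, 1], 3], dm[pairs[, 1], 2],
             dm[pairs[, 1], 1], pairs[, 2])
  pairs <- pairs[o, , drop = FALSE]
  usedD <- logical(nrow(dm)); usedR <- logical(nrow(rm_))
  out <- empty
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (usedD[i] || usedR[j]) next
    usedD[i] <- TRUE; usedR[j] <- TRUE
    out <- rbind(out, data.frame(det = i, ref = j, dist = D[i, j]))
  }
  out
}

asCoordDf <- function(x) {
  if (is(x, "MarkerSet")) markers(x) else as.data.frame(x)
}

#' Precision and recall (percent)
#'
#' \code{P = 100 * matched / detected} (0 when nothing was detected) and
#' \code{R = 100 * matched / reference} (0 when the reference is empty).
#'
#' @param matching a matching data.frame from \code{\link{matchMarkers}}, or
#'   the number of matched pairs.
#' @param nDetected,nReference totals.
#' @return Named numeric \code{c(precision =, recall =)} in percent.
#' @export
precisionRecall <- function(matching, nDetected, nReference) {
  nm <- if (is.data.frame(matching)) nrow(matching) else matching
  stopifnot(nm >= 0, nDetected >= 0, nReference >= 0,
            nm <= nDetected || nDetected == 0,
            nm <= nReference || nReference == 0)
  c(precision = if (nDetected > 0) 100 * nm / nDetected else 0,
    recall = if (nReference > 0) 100 * nm / nReference else 0)
}

#' F-measure (percent)
#'
#' Harmonic mean \code{F = 2PR / (P + R)}; 0 when \code{P + R = 0}.
#'
#' @param precision,recall percentages in [0, 100].
#' @return F-measure in percent.
#' @export
fMeasure <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 100),
            all(recall >= 0 & recall <= 100))
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-region evaluation report
#'
#' Scores each region's detections against its reference annotations and
#' appends an \code{AVERAGE} row of unweighted per-region means. Percentages
#' are reported to 2 decimals with half-up rounding.
#'
#' @param regions named list of regions, each a list with components
#'   \code{detected} and \code{reference} (\linkS4class{MarkerSet}s or
#'   coordinate data.frames).
#' @param box,voxelSize passed to \code{\link{matchMarkers}}.
#' @return data.frame with columns \code{region, n_reference, n_detected,
#'   n_matched, precision, recall, f} (percent, 2 decimals).
#' @export
regionReport <- function(regions, box = c(7, 7, 5),
                         voxelSize = c(80, 80, 400)) {
  stopifnot(length(regions) >= 1)
  nm <- names(regions) %||% paste0("Region ", seq_along(regions))
  if (is.null(names(regions))) names(regions) <- nm
  rows <- lapply(seq_along(regions), function(i) {
    rg <- regions[[i]]
    d <- asCoordDf(rg$detected); r <- asCoordDf(rg$reference)
    mt <- matchMarkers(d, r, box, voxelSize)
    pr <- precisionRecall(mt, nrow(d), nrow(r))
    f <- fMeasure(pr["precision"], pr["recall"])
    data.frame(region = names(regions)[i], n_reference = nrow(r),
               n_detected = nrow(d), n_matched = nrow(mt),
               precision = roundHalfUp(pr[["precision"]]),
               recall = roundHalfUp(pr[["recall"]]),
               f = roundHalfUp(f))
  })
  rep_ <- do.call(rbind, rows)
  avg <- data.frame(region = "AVERAGE",
                    n_reference = sum(rep_$n_reference),
                    n_detected = sum(rep_$n_detected),
                    n_matched = sum(rep_$n_matched),
                    precision = roundHalfUp(mean(rep_$precision)),
                    recall = roundHalfUp(mean(rep_$recall)),
                    f = roundHalfUp(mean(rep_$f)))
  rbind(rep_, avg)
}
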