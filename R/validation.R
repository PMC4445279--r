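# Multi-channel co-localization: synaptic markers must sit near the neuron.
#
# Staining artifacts look like dim puncta but float off the axon/dendrite, so
# detected centers lacking morphology-channel foreground within a centered
# proximity box are discarded.

#' Foreground mask of the morphology channel
#'
#' Segments the axon/dendrite structure with the pseudo-3D RATS segmentation
#' parameterization (the nominal, non-permissive one), then removes
#' foreground objects below \code{minSize} voxels -- the same small-object
#' noise rule applied to the synapse segmentation -- so isolated noise
#' speckles cannot validate stray markers.
#'
#' @param morphology the morphology-channel \linkS4class{VolumeStack}.
#' @param params a \code{\link{ratsParams}} list.
#' @param minSize minimum connected-foreground size kept (default 8; 0
#'   disables the cleanup).
#' @param ... passed to \code{\link{ratsMask}}.
#' @return Logical foreground array \code{[y, x, z]}.
#' @export
morphologyForeground <- function(morphology, params = ratsParams(),
                                 minSize = 8, ...) {
  m <- ratsMask(morphology, params, ...)
  if (minSize > 0 && any(m)) {
    m <- labelArray(connectedComponents26(m, minSize = minSize,
                                          voxelSize = voxelSize(morphology))) > 0
  }
  m
}

#' Co-localization filter against the morphology channel
#'
#' A marker is kept iff at least one foreground morphology voxel lies within
#' the centered proximity box (default 9 x 9 x 5, i.e. |dx| <= 4, |dy| <= 4,
#' |dz| <= 2). Kept markers gain status \code{validated}. The filter is
#' idempotent and never adds markers.
#'
#' @param markerSet a \linkS4class{MarkerSet}.
#' @param morphMask logical morphology foreground array.
#' @param box proximity box \code{(x, y, z)}, all odd.
#' @return The filtered \linkS4class{MarkerSet}.
#' @export
colocalizeFilter <- function(markerSet, morphMask, box = c(9, 9, 5)) {
  stopifnot(is(markerSet, "MarkerSet"))
  stopIfNotOdd(box, "box")
  m <- markers(markerSet)
  if (!nrow(m)) return(markerSet)
  near <- dilateMask3d(morphMask, as.integer(box))
  keep <- near[coordToLinear(dim(morphMask), m$x, m$y, m$z)]
  out <- m[keep, , drop = FALSE]
  out$status <- ifelse(hasStatus(out$status, "validated"), out$status,
                       addStatus(out$status, "validated"))
  MarkerSet(out)
}
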