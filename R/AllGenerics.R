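# Generics and accessor/show methods for the core classes.

#' @describeIn VolumeStack-class intensity array accessor.
#' @param object,x a \code{VolumeStack}.
#' @export
setGeneric("stackData", function(object) standardGeneric("stackData"))

#' @export
setMethod("stackData", "VolumeStack", function(object) object@data)

#' @describeIn VolumeStack-class voxel size accessor, \code{(dx, dy, dz)} nm.
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @export
setMethod("voxelSize", "VolumeStack", function(object) object@voxelSize)

#' @describeIn VolumeStack-class channel name accessor.
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))

#' @export
setMethod("channelName", "VolumeStack", function(object) object@channelName)

#' @describeIn VolumeStack-class dimensions \code{(Y, X, Z)} of the grid.
#' @export
setMethod("dim", "VolumeStack", function(x) dim(x@data))

setMethod("show", "VolumeStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeStack '%s': %d x %d x %d (x,y,z), voxel %g x %g x %g nm\n",
              object@channelName, d[2], d[1], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@data), max(object@data)))
})

#' @describeIn MarkerSet-class marker table accessor (data.frame with columns
#'   \code{x, y, z, score, status}).
#' @param object a \code{MarkerSet}.
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))

#' @export
setMethod("markers", "MarkerSet", function(object) object@markers)

#' @describeIn MarkerSet-class number of markers.
#' @export
setGeneric("nMarkers", function(object) standardGeneric("nMarkers"))

#' @export
setMethod("nMarkers", "MarkerSet", function(object) nrow(object@markers))

#' @describeIn MarkerSet-class coordinate matrix (columns \code{x, y, z}).
#' @export
setGeneric("markerCoords", function(object) standardGeneric("markerCoords"))

#' @export
setMethod("markerCoords", "MarkerSet", function(object)
  as.matrix(object@markers[, c("x", "y", "z"), drop = FALSE]))

setMethod("show", "MarkerSet", function(object) {
  cat(sprintf("MarkerSet with %d marker(s)\n", nrow(object@markers)))
  if (nrow(object@markers)) {
    print(utils::head(object@markers, 6))
    if (nrow(object@markers) > 6) cat("  ...\n")
  }
})

#' @describeIn Roi3D-class ROI intensity array accessor.
#' @param object a \code{Roi3D}.
#' @export
setGeneric("roiData", function(object) standardGeneric("roiData"))

#' @export
setMethod("roiData", "Roi3D", function(object) object@data)

#' @describeIn Roi3D-class class label accessor.
#' @export
setGeneric("roiLabel", function(object) standardGeneric("roiLabel"))

#' @export
setMethod("roiLabel", "Roi3D", function(object) object@label)

setMethod("show", "Roi3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Roi3D %d x %d x %d (x,y,z) at (%d, %d, %d), label: %s\n",
              d[2], d[1], d[3], object@center[1], object@center[2],
              object@center[3], object@label))
})

#' @describeIn LabeledObjects-class label array accessor.
#' @param object a \code{LabeledObjects}.
#' @export
setGeneric("labelArray", function(object) standardGeneric("labelArray"))

#' @export
setMethod("labelArray", "LabeledObjects", function(object) object@labels)

#' @describeIn LabeledObjects-class per-object statistics table.
#' @export
setGeneric("objectStats", function(object) standardGeneric("objectStats"))

#' @export
setMethod("objectStats", "LabeledObjects", function(object) object@stats)

#' @describeIn LabeledObjects-class number of labeled objects.
#' @export
setGeneric("nObjects", function(object) standardGeneric("nObjects"))

#' @export
setMethod("nObjects", "LabeledObjects", function(object) nrow(object@stats))

setMethod("show", "LabeledObjects", function(object) {
  cat(sprintf("LabeledObjects: %d object(s)", nrow(object@stats)))
  if (nrow(object@stats))
    cat(sprintf(", sizes %d..%d voxels", min(object@stats$voxel_count),
                max(object@stats$voxel_count)))
  cat("\n")
})

setMethod("show", "MlpModel", function(object) {
  cat(sprintf(
    "MlpModel: %d features -> %d hidden -> 1, trained %d epoch(s), train acc %.3f\n",
    ncol(object@W1) - 1, nrow(object@W1), object@meta$epochs_run,
    object@meta$train_accuracy))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene: %d true centers, %d artifact(s), %d morphology voxels\n",
    nMarkers(object@trueCenters), nMarkers(object@artifactCenters),
    sum(object@morphologyMask)))
})
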