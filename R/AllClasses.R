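# S4 classes for the synapse quantification pipeline.
#
# Coordinate convention used throughout the package: voxel coordinates are
# 0-based integer triples (x, y, z), with z the slice index. Arrays are stored
# [y, x, z] (row = y, column = x, slice = z). A box "a x b x c" always means
# extent a in x, b in y, c in z, centered on a voxel, i.e. |dx| <= (a-1)/2 etc.

#' VolumeStack: a single-channel 3D intensity grid
#'
#' Holds one channel of a confocal stack as a numeric array indexed
#' \code{[y, x, z]} together with the physical voxel size in nanometres.
#' Intensities must be nonnegative. Confocal stacks are typically anisotropic
#' (dz larger than dx = dy), which downstream stages exploit, but this is not
#' enforced.
#'
#' @slot data numeric 3D array \code{[y, x, z]} of nonnegative intensities.
#' @slot voxelSize numeric length-3 \code{(dx, dy, dz)} in nm.
#' @slot channelName character label for the channel.
#' @aliases VolumeStack
#' @exportClass VolumeStack
setClass("VolumeStack",
  representation(data = "array", voxelSize = "numeric",
                 channelName = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3)
      msg <- c(msg, "data must be a 3D array [y, x, z]")
    else if (any(dim(object@data) < 1))
      msg <- c(msg, "all dimensions must be >= 1")
    if (any(object@data < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be nonnegative")
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be three positive values (dx, dy, dz)")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a VolumeStack
#'
#' @param data numeric 3D array \code{[y, x, z]}; a matrix is promoted to a
#'   single-slice stack.
#' @param voxelSize \code{(dx, dy, dz)} in nm; default 80 x 80 x 400 nm, a
#'   typical laser-scanning confocal voxel.
#' @param channelName optional channel label.
#' @return A \linkS4class{VolumeStack}.
#' @examples
#' v <- VolumeStack(array(0, dim = c(8, 8, 4)))
#' dim(stackData(v))
#' @export
VolumeStack <- function(data, voxelSize = c(80, 80, 400), channelName = "") {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  new("VolumeStack", data = data, voxelSize = as.numeric(voxelSize),
      channelName = channelName)
}

#' MarkerSet: voxel-coordinate markers with provenance
#'
#' An ordered collection of voxel coordinates marking (candidate) synapse
#' centers, each with an optional score and a provenance status set drawn from
#' \code{raw}, \code{classified}, \code{shifted}, \code{merged},
#' \code{validated} (stored as a semicolon-joined string).
#'
#' @slot markers data.frame with columns \code{x, y, z} (0-based integers),
#'   \code{score} (numeric), \code{status} (character).
#' @aliases MarkerSet
#' @exportClass MarkerSet
setClass("MarkerSet",
  representation(markers = "data.frame"),
  validity = function(object) {
    m <- object@markers
    need <- c("x", "y", "z", "score", "status")
    if (!all(need %in% names(m)))
      return(sprintf("markers must have columns %s", paste(need, collapse = ", ")))
    if (nrow(m)) {
      xyz <- as.matrix(m[, c("x", "y", "z")])
      if (any(!is.finite(xyz)) || any(xyz < 0) || any(xyz != round(xyz)))
        return("coordinates must be nonnegative integers")
    }
    TRUE
  }
)

#' Construct a MarkerSet
#'
#' @param x,y,z integer 0-based voxel coordinates (vectors of equal length),
#'   or \code{x} may be a data.frame/matrix with columns \code{x, y, z} and
#'   optionally \code{score}, \code{status}.
#' @param score numeric scores (recycled; default \code{NA}).
#' @param status character status strings (recycled; default \code{""}).
#' @return A \linkS4class{MarkerSet}.
#' @examples
#' MarkerSet(x = c(3, 10), y = c(4, 11), z = c(1, 2))
#' @export
MarkerSet <- function(x = integer(), y = integer(), z = integer(),
                      score = NA_real_, status = "") {
  if (is.data.frame(x) || is.matrix(x)) {
    df <- as.data.frame(x)
    score <- df$score %||% NA_real_
    status <- df$status %||% ""
    y <- df$y; z <- df$z; x <- df$x
  }
  n <- length(x)
  m <- data.frame(x = as.integer(round(x)), y = as.integer(round(y)),
                  z = as.integer(round(z)),
                  score = rep_len(as.numeric(score), n),
                  status = rep_len(as.character(status), n),
                  stringsAsFactors = FALSE)
  new("MarkerSet", markers = m)
}

#' Roi3D: an odd-sized sub-volume around a center voxel
#'
#' Training and prediction operate on small regions of interest centered on a
#' voxel; the default 9 x 9 x 3 size matches the training ROI geometry. Voxels
#' outside the parent volume are filled by mirror reflection.
#'
#' @slot data numeric array \code{[y, x, z]} of odd dimensions.
#' @slot center integer \code{(x, y, z)}, 0-based, in the parent volume.
#' @slot label one of \code{"positive"}, \code{"negative"}, \code{"unlabeled"}.
#' @aliases Roi3D
#' @exportClass Roi3D
setClass("Roi3D",
  representation(data = "array", center = "integer", label = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3 || any(d %% 2 != 1))
      return("ROI dimensions must be odd (w, h, d)")
    if (!object@label %in% c("positive", "negative", "unlabeled"))
      return("label must be positive, negative or unlabeled")
    TRUE
  }
)

#' ThresholdField: per-pixel RATS threshold surface for one slice
#'
#' @slot field numeric matrix of per-pixel thresholds.
#' @slot leafCenters list with components \code{y}, \code{x}: 0-based centers
#'   of the quadtree leaflets used for interpolation.
#' @slot leafThresholds numeric matrix of leaflet thresholds (rows follow
#'   \code{leafCenters$y}, columns \code{leafCenters$x}).
#' @slot params the \code{RatsParams} the field was built with.
#' @aliases ThresholdField
#' @exportClass ThresholdField
setClass("ThresholdField",
  representation(field = "matrix", leafCenters = "list",
                 leafThresholds = "matrix", params = "list"))

#' LabeledObjects: integer-labeled 3D connected components
#'
#' Labels are contiguous 1..L in decreasing size order; background is 0.
#' Per-object statistics include voxel count, centroid (0-based, possibly
#' fractional), bounding box, the id of the guiding marker (after splitting)
#' and an \code{unsplittable} flag.
#'
#' @slot labels integer 3D array of object labels.
#' @slot stats data.frame of per-object statistics.
#' @slot voxelSize numeric \code{(dx, dy, dz)} in nm.
#' @aliases LabeledObjects
#' @exportClass LabeledObjects
setClass("LabeledObjects",
  representation(labels = "array", stats = "data.frame",
                 voxelSize = "numeric"))

#' MlpModel: a trained windowed-momentum multilayer perceptron
#'
#' A single-hidden-layer sigmoid network for binary classification of feature
#' vectors, trained by backpropagation with windowed momentum. Prediction is
#' deterministic given the stored weights; inputs are standardized with the
#' training-set per-dimension mean and standard deviation stored in the model.
#'
#' @slot W1 hidden-layer weights, \code{hidden x (d + 1)} (first column bias).
#' @slot W2 output weights, \code{1 x (hidden + 1)} (first entry bias).
#' @slot center,scale per-feature standardization constants.
#' @slot config the \code{mlpConfig()} list used for training.
#' @slot chain the algorithm chain (extractors + classifier) this model is
#'   part of, or an empty list for bare feature-space models.
#' @slot meta list with seed, epochs run and final training accuracy.
#' @aliases MlpModel
#' @exportClass MlpModel
setClass("MlpModel",
  representation(W1 = "matrix", W2 = "matrix", center = "numeric",
                 scale = "numeric", config = "list", chain = "list",
                 meta = "list"))

#' SceneParams and SyntheticScene: synthetic confocal ground truth
#'
#' \code{SyntheticScene} records the ground truth emitted by
#' \code{\link{generateScene}}: true synapse centers, a per-voxel ground-truth
#' label grid (nearest-center assignment under the blob covariance),
#' the binary morphology (tube) mask, planted artifact centers, and the
#' generating parameters.
#'
#' @slot trueCenters \linkS4class{MarkerSet} of true synapse centers.
#' @slot trueLabels integer array of ground-truth per-voxel labels.
#' @slot morphologyMask logical array of the tube mask.
#' @slot artifactCenters \linkS4class{MarkerSet} of planted off-tube artifacts.
#' @slot params the generating parameter list (see \code{\link{sceneParams}}).
#' @aliases SyntheticScene
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(trueCenters = "MarkerSet", trueLabels = "array",
                 morphologyMask = "array", artifactCenters = "MarkerSet",
                 params = "list"))
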