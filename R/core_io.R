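# Stack and marker I/O, ROI extraction.
#
# Multi-page grayscale TIFF is the interchange format for image stacks (page
# order = slice order), CSV (header x,y,z[,score,status]) for marker lists.

#' Read one channel of a multi-page TIFF stack
#'
#' Pages are read in file order and become z slices. Multi-sample (channel
#' interleaved) pages are supported: \code{channel} selects the sample; for
#' plain grayscale files only channel 0 exists.
#'
#' @param path path to a multi-page TIFF file.
#' @param channel 0-based channel index.
#' @param voxelSize physical voxel size \code{(dx, dy, dz)} in nm.
#' @param channelName optional channel label.
#' @return A \linkS4class{VolumeStack}; intensities are the raw stored sample
#'   values (integers for 8/16-bit files).
#' @seealso \code{\link{writeStack}}
#' @export
readStack <- function(path, channel = 0, voxelSize = c(80, 80, 400),
                      channelName = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("not a readable TIFF file: ", path, " (",
                           conditionMessage(e), ")", call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  pick <- function(p) {
    if (length(dim(p)) == 3) {
      if (channel < 0 || channel >= dim(p)[3])
        stop(sprintf("channel %d out of range (file has %d channel(s))",
                     channel, dim(p)[3]), call. = FALSE)
      p[, , channel + 1]
    } else {
      if (channel != 0)
        stop(sprintf("channel %d out of range (file has 1 channel)", channel),
             call. = FALSE)
      p
    }
  }
  slices <- lapply(pages, pick)
  d <- dim(slices[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  VolumeStack(arr, voxelSize = voxelSize, channelName = channelName)
}

#' Write a VolumeStack as a multi-page grayscale TIFF
#'
#' Intensities must be integers representable at the requested bit depth;
#' \code{readStack} of the written file returns bit-identical values.
#'
#' @param volume a \linkS4class{VolumeStack} with integer intensities.
#' @param path output file path.
#' @param bitsPerSample 8 or 16.
#' @return Invisibly, \code{path}.
#' @export
writeStack <- function(volume, path, bitsPerSample = 16) {
  stopifnot(is(volume, "VolumeStack"), bitsPerSample %in% c(8, 16))
  a <- stackData(volume)
  mx <- 2^bitsPerSample - 1
  if (any(a != round(a)) || any(a > mx))
    stop("intensities must be integers in [0, ", mx, "] for ",
         bitsPerSample, "-bit output", call. = FALSE)
  pages <- lapply(seq_len(dim(a)[3]), function(z) a[, , z] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample)
  invisible(path)
}

#' Extract an odd-sized ROI around a voxel
#'
#' Positions outside the volume are filled by mirror reflection (without edge
#' repetition), so e.g. for a depth-3 ROI centered on slice z = 0 the missing
#' bottom plane mirrors plane z = 1. Mirroring avoids the artificial dark
#' borders a constant fill would feed into the feature extractor.
#'
#' @param volume a \linkS4class{VolumeStack}.
#' @param center 0-based \code{(x, y, z)} voxel, inside the volume.
#' @param size \code{(w, h, d)} extents in x, y, z; all odd. Default
#'   \code{c(9, 9, 3)}, the training ROI geometry.
#' @param label class label to attach (\code{"positive"}, \code{"negative"}
#'   or \code{"unlabeled"}).
#' @return A \linkS4class{Roi3D}.
#' @export
extractRoi <- function(volume, center, size = c(9, 9, 3),
                       label = "unlabeled") {
  stopifnot(is(volume, "VolumeStack"), length(center) == 3, length(size) == 3)
  stopIfNotOdd(size, "ROI")
  d <- dim(volume@data)
  center <- as.integer(round(center))
  if (center[1] < 0 || center[1] >= d[2] || center[2] < 0 ||
      center[2] >= d[1] || center[3] < 0 || center[3] >= d[3])
    stop("center outside the volume", call. = FALSE)
  h <- (size - 1) / 2
  xs <- mirrorIdx(center[1] + (-h[1]:h[1]), d[2]) + 1L
  ys <- mirrorIdx(center[2] + (-h[2]:h[2]), d[1]) + 1L
  zs <- mirrorIdx(center[3] + (-h[3]:h[3]), d[3]) + 1L
  new("Roi3D", data = volume@data[ys, xs, zs, drop = FALSE],
      center = center, label = label)
}

#' Write / read marker CSV files
#'
#' The CSV has header \code{x,y,z,score,status}; coordinates round-trip
#' exactly and scores to full double precision. Malformed or negative
#' coordinate rows raise an error naming the offending line.
#'
#' @param markerSet a \linkS4class{MarkerSet}.
#' @param path CSV file path.
#' @return \code{writeMarkers} invisibly returns \code{path};
#'   \code{readMarkers} returns a \linkS4class{MarkerSet}.
#' @export
writeMarkers <- function(markerSet, path) {
  stopifnot(is(markerSet, "MarkerSet"))
  utils::write.csv(markerSet@markers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMarkers
#' @export
readMarkers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = "NA")
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop("marker CSV must have columns x,y,z", call. = FALSE)
  for (cc in need) {
    v <- df[[cc]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))) |
                   suppressWarnings(as.numeric(v)) < 0 |
                   suppressWarnings(as.numeric(v)) != round(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop(sprintf("malformed marker at line %d (column %s)", bad[1] + 1L, cc),
           call. = FALSE)
  }
  MarkerSet(x = as.integer(df$x), y = as.integer(df$y), z = as.integer(df$z),
            score = if (!is.null(df$score)) as.numeric(df$score) else NA_real_,
            status = if (!is.null(df$status)) {
              s <- as.character(df$status); s[is.na(s)] <- ""; s
            } else "")
}

# Append a status flag to marker status strings.
addStatus <- function(status, flag) {
  ifelse(status == "" | is.na(status), flag, paste(status, flag, sep = ";"))
}

hasStatus <- function(status, flag) {
  if (!length(status)) return(logical(0))
  status <- as.character(status)
  vapply(strsplit(ifelse(is.na(status), "", status), ";", fixed = TRUE),
         function(s) flag %in% s, logical(1))
}
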