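# End-to-end pipeline orchestration.
#
# Stage order: split channels -> RATS over-mask -> masked local maxima ->
# model classification -> mean-shift + merge -> RATS segmentation mask +
# 26-connected components -> marker-guided clump splitting -> (optional)
# morphology co-localization -> quantification -> (optional) evaluation.

#' Pipeline configuration
#'
#' A nested list mirroring the per-stage parameter constructors. All
#' randomness (model initialization, fold assignment) flows from the single
#' top-level \code{seed}.
#'
#' @param rats \code{\link{ratsParams}} for the synapse channel. The default
#'   \code{minNoise = 40} is twice the benchmark scene's noise sd: the
#'   validity floor \code{(scalingFactor * minNoise)^2} per gradient-bearing
#'   pixel then sits well above the squared Sobel magnitude of the scene's
#'   correlated noise (so signal-free leaflets defer to their parent) while
#'   staying below the gradient mass of leaflets containing puncta (so those
#'   keep their local threshold).
#' @param morphologyRats \code{\link{ratsParams}} for the morphology
#'   channel. Its default \code{minNoise = 80} (4 x the scene noise sd) is
#'   stricter than the synapse channel's: the near-zero clipped background
#'   concentrates gradient energy in sparse spikes, which shrinks the
#'   per-gradient-pixel validity floor, so only the strong membrane edge
#'   should be allowed to define local thresholds.
#' @param ratsReference reference slice passed to \code{\link{ratsMask}}.
#' @param ratsApplyReferenceField if \code{TRUE} (default), every slice is
#'   thresholded with the reference (middle) slice's field. Boundary slices
#'   of a confocal stack are typically dark and signal-free; recomputing the
#'   threshold there over-detects, which anchoring to the middle slice
#'   avoids.
#' @param detection a \code{\link{detectionParams}} list.
#' @param haar a \code{\link{haarConfig}} list.
#' @param mlp a \code{\link{mlpConfig}} list.
#' @param colocalizationBox proximity box for \code{\link{colocalizeFilter}}.
#' @param evaluationBox proximity box for \code{\link{matchMarkers}}.
#' @param sizeRange object size bounds for \code{\link{quantifyObjects}}.
#' @param nTrainPos,nTrainNeg training ROIs sampled when training from a
#'   synthetic scene.
#' @param seed top-level RNG seed.
#' @return A named list.
#' @export
pipelineConfig <- function(rats = ratsParams(leafletSize = 16, minNoise = 40,
                                             scalingFactor = 3, minDepth = 5),
                           morphologyRats = ratsParams(leafletSize = 16,
                                                       minNoise = 80,
                                                       scalingFactor = 3,
                                                       minDepth = 5),
                           ratsReference = "middle",
                           ratsApplyReferenceField = TRUE,
                           detection = detectionParams(),
                           haar = haarConfig(), mlp = NULL,
                           colocalizationBox = c(9, 9, 5),
                           evaluationBox = c(7, 7, 5),
                           sizeRange = c(8, 1000),
                           nTrainPos = 25, nTrainNeg = 25, seed = 1) {
  list(rats = rats, morphologyRats = morphologyRats,
       ratsReference = ratsReference,
       ratsApplyReferenceField = ratsApplyReferenceField,
       detection = detection, haar = haar,
       mlp = mlp %||% mlpConfig(seed = seed),
       colocalizationBox = colocalizationBox,
       evaluationBox = evaluationBox, sizeRange = sizeRange,
       nTrainPos = nTrainPos, nTrainNeg = nTrainNeg, seed = seed)
}

#' Run the full detection / splitting / validation pipeline
#'
#' Executes every stage on a synapse channel (plus optional morphology
#' channel), using either a pre-trained model or training markers. The
#' "model output" detections are the classified, mean-shifted and merged
#' markers. Splitting partitions each clump's voxels into per-synapse
#' supports for quantification; detected positions stay the mean-shifted
#' markers (already local centers of mass), with markers of split clumps
#' flagged "split".
#'
#' @param synapse the synapse-channel \linkS4class{VolumeStack}.
#' @param morphology optional morphology-channel \linkS4class{VolumeStack};
#'   when absent the co-localization stage is skipped.
#' @param model an \linkS4class{MlpModel}, or \code{NULL} to train from
#'   \code{trainPositives}/\code{trainNegatives}.
#' @param trainPositives,trainNegatives \linkS4class{MarkerSet}s of training
#'   annotations (required when \code{model} is \code{NULL}).
#' @param reference optional \linkS4class{MarkerSet} of reference centers;
#'   when given, model-output and after-splitting detections are scored.
#' @param config a \code{\link{pipelineConfig}} list.
#' @param outputDir optional directory; when given, marker CSVs, the split
#'   label TIFF, a stats CSV and a JSON manifest are written there.
#' @param verbose print per-stage counts.
#' @return List with the per-stage artifacts: \code{model},
#'   \code{candidates}, \code{classified}, \code{modelMarkers} (after mean
#'   shift and merging), \code{objects} (after splitting),
#'   \code{refinedMarkers}, \code{validatedMarkers} (or \code{NULL}),
#'   \code{quantification}, \code{evaluation} (or \code{NULL}) and
#'   \code{log} (per-stage counts).
#' @export
runPipeline <- function(synapse, morphology = NULL, model = NULL,
                        trainPositives = NULL, trainNegatives = NULL,
                        reference = NULL, config = pipelineConfig(),
                        outputDir = NULL, verbose = FALSE) {
  stopifnot(is(synapse, "VolumeStack"))
  if (!is.null(morphology) &&
      !identical(dim(synapse@data), dim(morphology@data)))
    stop("synapse and morphology channel shapes differ", call. = FALSE)
  log <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  if (is.null(model)) {
    if (is.null(trainPositives) || is.null(trainNegatives))
      stop("need either a model or training markers", call. = FALSE)
    rois <- assembleTrainingSet(synapse, trainPositives, trainNegatives,
                                config$detection$roiSize)
    X <- featureMatrix(rois, list(list(id = "haar3d", config = config$haar)))
    y <- vapply(rois, roiLabel, "") == "positive"
    model <- trainMlp(X, y, config$mlp,
                      chain = algorithmChain("haar3d", "mlp"))
    say("trained MLP on %d ROIs (train acc %.3f)", length(rois),
        model@meta$train_accuracy)
  }

  over <- ratsMask(synapse, overmaskParams(config$rats),
                   reference = config$ratsReference,
                   applyReferenceField = config$ratsApplyReferenceField)
  log$overmask_voxels <- sum(over)
  cand <- localMaxima(synapse, over, config$detection$maximaNeighborhood)
  log$candidates <- nMarkers(cand)
  say("%d candidate local maxima", nMarkers(cand))

  cls <- classifyCandidates(model, synapse, cand, config$detection$roiSize)
  log$classified <- nMarkers(cls)
  say("%d candidates classified positive", nMarkers(cls))

  shifted <- refineMarkers(synapse, cls, config$detection)
  modelMarkers <- mergeClose(shifted,
                             voxelSize = voxelSize(synapse),
                             params = config$detection)
  log$model_markers <- nMarkers(modelMarkers)
  say("%d markers after mean shift + merge", nMarkers(modelMarkers))

  seg <- ratsMask(synapse, config$rats, reference = config$ratsReference,
                  applyReferenceField = config$ratsApplyReferenceField)
  objects0 <- connectedComponents26(seg, minSize = config$sizeRange[1],
                                    voxelSize = voxelSize(synapse))
  log$segmented_objects <- nObjects(objects0)
  objects <- splitObjects(objects0, modelMarkers, voxelSize(synapse))
  log$objects_after_split <- nObjects(objects)
  say("%d objects (%d after splitting)", nObjects(objects0), nObjects(objects))

  refinedMarkers <- refinedFromSplit(objects, modelMarkers)
  log$refined_markers <- nMarkers(refinedMarkers)

  validatedMarkers <- NULL
  if (!is.null(morphology)) {
    mmask <- morphologyForeground(morphology, config$morphologyRats,
                                  reference = config$ratsReference,
                                  applyReferenceField =
                                    config$ratsApplyReferenceField)
    validatedMarkers <- colocalizeFilter(refinedMarkers, mmask,
                                         config$colocalizationBox)
    log$validated_markers <- nMarkers(validatedMarkers)
    say("%d markers kept by co-localization", nMarkers(validatedMarkers))
  } else {
    say("no morphology channel: co-localization skipped")
    log$validation <- "skipped"
  }

  quantification <- quantifyObjects(objects, config$sizeRange)
  log$objects_in_size_range <- quantification$count

  evaluation <- NULL
  if (!is.null(reference)) {
    evaluation <- list(
      model = scoreAgainst(modelMarkers, reference, config$evaluationBox,
                           voxelSize(synapse)),
      splitting = scoreAgainst(refinedMarkers, reference,
                               config$evaluationBox, voxelSize(synapse)))
    if (!is.null(validatedMarkers))
      evaluation$validated <- scoreAgainst(validatedMarkers, reference,
                                           config$evaluationBox,
                                           voxelSize(synapse))
  }

  out <- list(model = model, candidates = cand, classified = cls,
              modelMarkers = modelMarkers, objects = objects,
              refinedMarkers = refinedMarkers,
              validatedMarkers = validatedMarkers,
              quantification = quantification, evaluation = evaluation,
              log = log, config = config)
  if (!is.null(outputDir)) writePipelineOutputs(out, outputDir)
  out
}

# After-splitting detections. Splitting partitions clump voxels into
# per-synapse supports (reported by quantifyObjects); the detected center
# positions remain the mean-shifted markers, which already estimate the
# local center of mass on each punctum peak -- reassigning a marker to its
# whole-child centroid can only move it off-peak whenever the child still
# contains an unresolved second punctum. Markers whose clump was actually
# split gain status "split".
refinedFromSplit <- function(objectsAfter, modelMarkers) {
  mk <- markers(modelMarkers)
  if (!nrow(mk)) return(modelMarkers)
  st <- objectStats(objectsAfter)
  splitIds <- st$marker_id[st$from_split & !is.na(st$marker_id)]
  if (length(splitIds)) {
    hit <- seq_len(nrow(mk)) %in% splitIds
    mk$status[hit] <- addStatus(mk$status[hit], "split")
  }
  MarkerSet(mk)
}

scoreAgainst <- function(detected, reference, box, voxelSize) {
  d <- asCoordDf(detected); r <- asCoordDf(reference)
  mt <- matchMarkers(d, r, box, voxelSize)
  pr <- precisionRecall(mt, nrow(d), nrow(r))
  list(n_detected = nrow(d), n_reference = nrow(r), n_matched = nrow(mt),
       precision = pr[["precision"]], recall = pr[["recall"]],
       f = fMeasure(pr[["precision"]], pr[["recall"]]))
}

#' Write pipeline artifacts to a directory
#'
#' Writes the model-output and refined marker CSVs, the split label image as
#' a 16-bit TIFF, a per-object stats CSV and a JSON manifest (configuration
#' hash, seed and per-stage counts) sufficient to re-run identically.
#'
#' @param result a \code{\link{runPipeline}} result.
#' @param dir output directory (created if missing).
#' @return Invisibly, \code{dir}.
#' @export
writePipelineOutputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMarkers(result$modelMarkers, file.path(dir, "markers_model.csv"))
  writeMarkers(result$refinedMarkers, file.path(dir, "markers_refined.csv"))
  if (!is.null(result$validatedMarkers))
    writeMarkers(result$validatedMarkers,
                 file.path(dir, "markers_validated.csv"))
  lab <- labelArray(result$objects)
  writeStack(VolumeStack(array(as.numeric(lab), dim = dim(lab))),
             file.path(dir, "labels_split.tif"))
  utils::write.csv(objectStats(result$objects),
                   file.path(dir, "object_stats.csv"), row.names = FALSE)
  tmp <- tempfile()
  saveRDS(result$config, tmp)
  manifest <- list(config_hash = unname(tools::md5sum(tmp)),
                   seed = result$config$seed, log = result$log)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the benchmark scene end-to-end
#'
#' Generates the default synthetic benchmark scene (optionally reseeded),
#' samples 25 positive + 25 negative training ROIs, trains the default
#' haar3d + MLP chain and runs the full pipeline against the scene's ground
#' truth.
#'
#' @param seed seed for scene generation, training-ROI sampling and model
#'   initialization.
#' @param params a \code{\link{sceneParams}} list; its seed is overridden by
#'   \code{seed}.
#' @param config a \code{\link{pipelineConfig}} list; its seed is overridden.
#' @param verbose print per-stage counts.
#' @return The \code{\link{runPipeline}} result, plus components
#'   \code{scene}, \code{synapse}, \code{morphology}, \code{trainingRois}
#'   and \code{cvAccuracy} (5-fold chain cross-validation on the training
#'   set).
#' @export
runBenchmark <- function(seed = 42, params = sceneParams(),
                         config = pipelineConfig(), verbose = FALSE) {
  params$seed <- seed
  config$seed <- seed
  config$mlp$seed <- seed
  gen <- generateScene(params)
  rois <- sampleTrainingRois(gen$scene, gen$synapse,
                             nPos = config$nTrainPos,
                             nNeg = config$nTrainNeg, seed = seed)
  X <- featureMatrix(rois, list(list(id = "haar3d", config = config$haar)))
  y <- vapply(rois, roiLabel, "") == "positive"
  model <- trainMlp(X, y, config$mlp,
                    chain = algorithmChain("haar3d", "mlp"))
  cv <- crossValidate(algorithmChain("haar3d", "mlp"), rois, k = 5,
                      seed = seed)
  res <- runPipeline(gen$synapse, morphology = gen$morphology, model = model,
                     reference = trueCenters(gen$scene), config = config,
                     verbose = verbose)
  res$scene <- gen$scene
  res$synapse <- gen$synapse
  res$morphology <- gen$morphology
  res$trainingRois <- rois
  res$cvAccuracy <- cv
  res
}
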