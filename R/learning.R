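# Training-set assembly, the windowed-momentum MLP, cross-validation and
# algorithm-chain comparison.
#
# The detector is a binary classifier of voxels: is this voxel the center of a
# synaptic punctum or not? Training ROIs (default 9 x 9 x 3) around annotated
# positive/negative voxels are turned into feature vectors by the chain's
# extractor(s) and classified; chains are ranked by stratified k-fold
# cross-validation accuracy.

#' MLP training configuration
#'
#' The network is a single hidden layer of sigmoid units with a sigmoid
#' output, trained by full-batch backpropagation on the mean squared error
#' with a windowed momentum term: each update is
#' \code{delta_w(t) = -eta * grad(t) + alpha * mean(delta_w(t-1), ...,
#' delta_w(t-W))}. With \code{window = 1} this reduces exactly to classical
#' momentum.
#'
#' @param hiddenUnits number of hidden units (default 16).
#' @param learningRate step size eta (default 0.05).
#' @param momentum momentum coefficient alpha (default 0.9).
#' @param window momentum window W, the number of past updates averaged
#'   (default 5).
#' @param epochs maximum training epochs (default 500).
#' @param tol early-stop tolerance on the mean squared error (default 1e-4).
#' @param seed RNG seed for weight initialization.
#' @return A validated named list.
#' @export
mlpConfig <- function(hiddenUnits = 16, learningRate = 0.05, momentum = 0.9,
                      window = 5, epochs = 500, tol = 1e-4, seed = 1) {
  stopifnot(hiddenUnits >= 1, learningRate > 0, momentum >= 0, window >= 1,
            epochs >= 1, tol >= 0)
  list(hiddenUnits = as.integer(hiddenUnits), learningRate = learningRate,
       momentum = momentum, window = as.integer(window),
       epochs = as.integer(epochs), tol = tol, seed = as.integer(seed))
}

#' Define an algorithm chain
#'
#' A chain is an ordered set of feature extractor(s) followed by exactly one
#' classifier (an optional feature-selector slot is accepted but no selector
#' is shipped). Classifier ids: \code{"mlp"} (the bespoke windowed-momentum
#' perceptron), \code{"dummy"} (majority class), and, when the corresponding
#' packages are installed, \code{"svm"} and \code{"rf"}.
#'
#' @param extractors list of \code{list(id =, config =)} extractor specs, or a
#'   character vector of ids (default configs).
#' @param classifier \code{list(id =, config =)} or a classifier id.
#' @param name optional display name; defaults to "extractor+classifier".
#' @return A chain object (named list, class \code{"AlgorithmChain"}).
#' @export
algorithmChain <- function(extractors = "haar3d", classifier = "mlp",
                           name = NULL) {
  if (is.character(extractors))
    extractors <- lapply(extractors, function(id) list(id = id, config = NULL))
  if (is.character(classifier)) classifier <- list(id = classifier,
                                                   config = NULL)
  stopifnot(length(extractors) >= 1, !is.null(classifier$id))
  if (is.null(name))
    name <- paste(c(vapply(extractors, `[[`, "", "id"), classifier$id),
                  collapse = "+")
  structure(list(extractors = extractors, classifier = classifier,
                 name = name), class = "AlgorithmChain")
}

#' Assemble a labeled training set of ROIs
#'
#' @param volume a \linkS4class{VolumeStack}.
#' @param positives,negatives \linkS4class{MarkerSet}s of center /
#'   non-center voxels; coordinates must be distinct across the two classes
#'   and inside the volume.
#' @param roiSize ROI extent \code{(w, h, d)}, all odd.
#' @return List of labeled \linkS4class{Roi3D}.
#' @export
assembleTrainingSet <- function(volume, positives, negatives,
                                roiSize = c(9, 9, 3)) {
  stopifnot(is(positives, "MarkerSet"), is(negatives, "MarkerSet"))
  pc <- markerCoords(positives); nc <- markerCoords(negatives)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  if (length(intersect(key(pc), key(nc))))
    stop("duplicate coordinates across positive and negative classes",
         call. = FALSE)
  c(lapply(seq_len(nrow(pc)), function(i)
      extractRoi(volume, pc[i, ], roiSize, label = "positive")),
    lapply(seq_len(nrow(nc)), function(i)
      extractRoi(volume, nc[i, ], roiSize, label = "negative")))
}

sigm <- function(x) 1 / (1 + exp(-x))

#' Train the windowed-momentum MLP
#'
#' Features are standardized per dimension (z-score from the training data;
#' constant dimensions get unit scale) and the standardization constants are
#' stored in the model. Training is deterministic under a fixed seed.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y labels: logical, 0/1, or \code{"positive"}/\code{"negative"}.
#' @param config a \code{\link{mlpConfig}} list.
#' @param chain optional chain annotation stored in the model.
#' @return An \linkS4class{MlpModel}.
#' @export
trainMlp <- function(X, y, config = mlpConfig(), chain = list()) {
  X <- as.matrix(X)
  y <- normalizeLabels(y)
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("training needs at least 2 samples in each of the two classes",
         call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  n <- nrow(Xs); d <- ncol(Xs); H <- config$hiddenUnits

  withSeed(config$seed, {
    W1 <- matrix(stats::runif(H * (d + 1), -1, 1) / sqrt(d + 1), H, d + 1)
    W2 <- matrix(stats::runif(H + 1, -1, 1) / sqrt(H + 1), 1, H + 1)
  })
  X1 <- t(cbind(1, Xs))                      # (d+1) x n
  hist1 <- list(); hist2 <- list()
  eta <- config$learningRate; alpha <- config$momentum; Wn <- config$window
  epochsRun <- 0
  for (ep in seq_len(config$epochs)) {
    Z1 <- sigm(W1 %*% X1)                    # H x n
    Z1b <- rbind(1, Z1)
    O <- sigm(W2 %*% Z1b)                    # 1 x n
    err <- O - matrix(y, 1, n)
    mse <- mean(err^2) / 2
    epochsRun <- ep
    if (mse < config$tol) break
    d2 <- err * O * (1 - O) / n              # 1 x n
    g2 <- d2 %*% t(Z1b)                      # 1 x (H+1)
    d1 <- (t(W2[, -1, drop = FALSE]) %*% d2) * Z1 * (1 - Z1)
    g1 <- d1 %*% t(X1)                       # H x (d+1)
    m1 <- if (length(hist1)) Reduce(`+`, hist1) / length(hist1) else 0
    m2 <- if (length(hist2)) Reduce(`+`, hist2) / length(hist2) else 0
    u1 <- -eta * g1 + alpha * m1
    u2 <- -eta * g2 + alpha * m2
    W1 <- W1 + u1; W2 <- W2 + u2
    hist1 <- c(hist1, list(u1)); if (length(hist1) > Wn) hist1 <- hist1[-1]
    hist2 <- c(hist2, list(u2)); if (length(hist2) > Wn) hist2 <- hist2[-1]
  }
  O <- sigm(W2 %*% rbind(1, sigm(W1 %*% X1)))
  acc <- mean((O > 0.5) == (y == 1))
  new("MlpModel", W1 = W1, W2 = W2, center = ctr, scale = scl,
      config = config, chain = if (inherits(chain, "AlgorithmChain"))
        unclass(chain) else chain,
      meta = list(seed = config$seed, epochs_run = epochsRun,
                  train_accuracy = acc))
}

normalizeLabels <- function(y) {
  if (is.character(y) || is.factor(y)) as.integer(as.character(y) == "positive")
  else as.integer(y > 0.5)
}

#' Predict with a trained MLP
#'
#' @param object an \linkS4class{MlpModel}.
#' @param features numeric vector or matrix (rows = samples) matching the
#'   training feature length.
#' @param ... unused.
#' @return data.frame with columns \code{score} (in [0, 1]) and \code{label}
#'   (\code{"positive"} iff score strictly exceeds 0.5; a score of exactly
#'   0.5 is negative).
#' @export
setMethod("predict", "MlpModel", function(object, features, ...) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1)
       else as.matrix(features)
  if (ncol(X) != ncol(object@W1) - 1)
    stop(sprintf("feature length %d does not match model input %d",
                 ncol(X), ncol(object@W1) - 1), call. = FALSE)
  Xs <- sweep(sweep(X, 2, object@center), 2, object@scale, "/")
  O <- as.numeric(sigm(object@W2 %*% rbind(1, sigm(object@W1 %*% t(cbind(1, Xs))))))
  data.frame(score = O, label = ifelse(O > 0.5, "positive", "negative"),
             stringsAsFactors = FALSE)
})

# --- classifier plugin interface -------------------------------------------

trainClassifierById <- function(id, X, y, config = NULL, seed = 1) {
  y01 <- normalizeLabels(y)
  switch(id,
    mlp = {
      cfg <- config %||% mlpConfig(seed = seed)
      cfg$seed <- cfg$seed %||% seed
      trainMlp(X, y01, cfg)
    },
    dummy = {
      maj <- as.integer(mean(y01) >= 0.5)
      structure(list(majority = maj), class = "dummyClassifier")
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("classifier 'svm' needs the e1071 package", call. = FALSE)
      e1071::svm(x = X, y = factor(y01, levels = c(0, 1)), probability = FALSE)
    },
    rf = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("classifier 'rf' needs the randomForest package", call. = FALSE)
      withSeed(seed, randomForest::randomForest(x = X,
        y = factor(y01, levels = c(0, 1))))
    },
    stop("unknown classifier id: ", id, call. = FALSE))
}

classifierScores <- function(clf, X) {
  X <- as.matrix(X)
  if (is(clf, "MlpModel")) return(predict(clf, X)$score)
  if (inherits(clf, "dummyClassifier")) return(rep(clf$majority, nrow(X)))
  as.numeric(as.character(stats::predict(clf, X)) == "1")
}

#' Stratified k-fold cross-validation of an algorithm chain
#'
#' Folds are stratified per class with sizes differing by at most one;
#' accuracy is pooled over all held-out predictions.
#'
#' @param chain an \code{\link{algorithmChain}}.
#' @param rois list of labeled \linkS4class{Roi3D} (labels
#'   \code{"positive"}/\code{"negative"}).
#' @param k number of folds (default 5); must be at least 2 and no larger
#'   than the smaller class.
#' @param seed RNG seed for the fold assignment.
#' @return Pooled cross-validation accuracy in [0, 1].
#' @export
crossValidate <- function(chain, rois, k = 5, seed = 1) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  labels <- vapply(rois, roiLabel, "")
  y <- as.integer(labels == "positive")
  if (length(unique(y)) < 2)
    stop("cross-validation needs both classes", call. = FALSE)
  if (min(table(y)) < k)
    stop("k exceeds the smallest class count", call. = FALSE)
  X <- featureMatrix(rois, chain$extractors)
  folds <- withSeed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  correct <- 0
  for (fold in seq_len(k)) {
    tr <- folds != fold; te <- !tr
    clf <- trainClassifierById(chain$classifier$id, X[tr, , drop = FALSE],
                               y[tr], chain$classifier$config, seed = seed)
    pr <- classifierScores(clf, X[te, , drop = FALSE]) > 0.5
    correct <- correct + sum(pr == (y[te] == 1))
  }
  correct / length(y)
}

#' Compare algorithm chains by cross-validation
#'
#' @param chains list of \code{\link{algorithmChain}} objects.
#' @param rois labeled ROI list.
#' @param k,seed passed to \code{\link{crossValidate}}.
#' @return data.frame (chain, accuracy) sorted by decreasing accuracy; ties
#'   keep the declaration order.
#' @export
compareChains <- function(chains, rois, k = 5, seed = 1) {
  stopifnot(length(chains) >= 1)
  acc <- vapply(chains, crossValidate, numeric(1), rois = rois, k = k,
                seed = seed)
  out <- data.frame(chain = vapply(chains, `[[`, "", "name"),
                    accuracy = acc, stringsAsFactors = FALSE)
  out[order(-out$accuracy), , drop = FALSE]
}

#' Serialize / load a trained MLP model
#'
#' The model (weights, standardization constants, configuration and chain) is
#' written as a single portable JSON file.
#'
#' @param model an \linkS4class{MlpModel}.
#' @param path JSON file path.
#' @return \code{writeModel} invisibly returns \code{path}; \code{readModel}
#'   returns the restored \linkS4class{MlpModel}.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "MlpModel"))
  obj <- list(W1 = model@W1, W2 = model@W2, center = model@center,
              scale = model@scale, config = model@config,
              chain = model@chain, meta = model@meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  revive <- function(cfg) {
    if (is.null(cfg) || !length(cfg)) return(NULL)
    lapply(cfg, function(v) if (is.list(v)) unlist(v) else v)
  }
  chain <- list()
  if (length(raw$chain)) {
    chain <- list(
      extractors = lapply(raw$chain$extractors, function(e)
        list(id = e$id, config = revive(e$config))),
      classifier = list(id = raw$chain$classifier$id,
                        config = revive(raw$chain$classifier$config)),
      name = raw$chain$name)
  }
  new("MlpModel", W1 = as.matrix(obj$W1), W2 = matrix(obj$W2, nrow = 1),
      center = as.numeric(obj$center), scale = as.numeric(obj$scale),
      config = obj$config, chain = chain, meta = as.list(obj$meta))
}
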