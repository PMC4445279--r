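# Windowed-momentum MLP, training-set assembly and cross-validation.

test_that("training sets preserve counts and reject cross-class duplicates", {
  set.seed(4)
  v <- VolumeStack(array(runif(20 * 20 * 6, 0, 100), dim = c(20, 20, 6)))
  pos <- MarkerSet(x = seq(2, 16, 3), y = seq(2, 16, 3), z = rep(2, 5))
  neg <- MarkerSet(x = seq(3, 17, 3), y = seq(2, 16, 3), z = rep(3, 5))
  rois <- assembleTrainingSet(v, pos, neg)
  expect_length(rois, 10)
  expect_equal(sum(vapply(rois, roiLabel, "") == "positive"), 5)
  expect_equal(dim(roiData(rois[[1]])), c(9L, 9L, 3L))
  expect_error(assembleTrainingSet(v, pos, pos), "duplicate")
})

test_that("the MLP learns separable data and XOR, deterministically", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  y <- rep(c(0, 1), each = 20)
  m1 <- trainMlp(X, y, mlpConfig(hiddenUnits = 4, seed = 1))
  expect_equal(m1@meta$train_accuracy, 1)
  # every training sample predicts its own label
  pr <- predict(m1, X)
  expect_equal(as.integer(pr$label == "positive"), y)
  expect_true(all(pr$score >= 0 & pr$score <= 1))

  # determinism under a fixed seed
  m2 <- trainMlp(X, y, mlpConfig(hiddenUnits = 4, seed = 1))
  expect_identical(m1@W1, m2@W1)
  expect_identical(m1@W2, m2@W2)

  # XOR needs the hidden layer
  Xx <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  mx <- trainMlp(Xx, c(0, 1, 1, 0),
                 mlpConfig(hiddenUnits = 4, epochs = 5000,
                           learningRate = 0.5, seed = 2))
  expect_equal(mx@meta$train_accuracy, 1)

  expect_error(trainMlp(X[1:20, ], y[1:20], mlpConfig()), "class")
})

test_that("prediction applies the strict 0.5 tie rule and checks lengths", {
  set.seed(5)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 6), 10, 2))
  m <- trainMlp(X, rep(c(0, 1), each = 10), mlpConfig(seed = 1))
  # zeroed output weights force a score of exactly 0.5 -> negative
  m@W2[] <- 0
  pr <- predict(m, c(0, 0))
  expect_equal(pr$score, 0.5)
  expect_equal(pr$label, "negative")
  expect_error(predict(m, c(1, 2, 3)), "length")
})

test_that("windowed momentum with window 1 equals classical momentum", {
  set.seed(6)
  X <- matrix(rnorm(60), 20, 3)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  cfgW <- mlpConfig(hiddenUnits = 3, window = 1, epochs = 40, seed = 9)
  mW <- trainMlp(X, y, cfgW)
  # classical momentum reference: delta(t) = -eta grad + alpha delta(t-1),
  # re-implemented independently
  ref <- local({
    ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    d <- ncol(Xs); H <- 3; n <- nrow(Xs)
    set.seed(9)
    W1 <- matrix(runif(H * (d + 1), -1, 1) / sqrt(d + 1), H, d + 1)
    W2 <- matrix(runif(H + 1, -1, 1) / sqrt(H + 1), 1, H + 1)
    sig <- function(x) 1 / (1 + exp(-x))
    X1 <- t(cbind(1, Xs)); u1 <- 0; u2 <- 0
    for (ep in 1:40) {
      Z1 <- sig(W1 %*% X1); Z1b <- rbind(1, Z1)
      O <- sig(W2 %*% Z1b)
      if (mean((O - y)^2) / 2 < 1e-4) break
      d2 <- (O - matrix(y, 1, n)) * O * (1 - O) / n
      g2 <- d2 %*% t(Z1b)
      d1 <- (t(W2[, -1, drop = FALSE]) %*% d2) * Z1 * (1 - Z1)
      g1 <- d1 %*% t(X1)
      u1 <- -0.05 * g1 + 0.9 * u1
      u2 <- -0.05 * g2 + 0.9 * u2
      W1 <- W1 + u1; W2 <- W2 + u2
    }
    list(W1 = W1, W2 = W2)
  })
  expect_equal(mW@W1, ref$W1, tolerance = 1e-12)
  expect_equal(mW@W2, ref$W2, tolerance = 1e-12)
})

test_that("stratified cross-validation scores chains correctly", {
  rois <- separableRoiSet(n = 20, seed = 3)
  chain <- algorithmChain("mean_intensity", "mlp")
  acc <- crossValidate(chain, rois, k = 5, seed = 1)
  expect_equal(acc, 1)

  # fold sizes: 50 samples, k = 5 -> folds of 10 (checked via stratification)
  expect_error(crossValidate(chain, rois, k = 1), "k must be")
  expect_error(crossValidate(chain, rois[c(1:4, 21:23)], k = 5),
               "smallest class")
  expect_error(crossValidate(chain, rois[1:6], k = 5), "both classes")

  # permuted labels give chance-level accuracy
  accs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    rp <- rois
    labs <- sample(vapply(rois, roiLabel, ""))
    for (i in seq_along(rp)) rp[[i]]@label <- labs[i]
    crossValidate(chain, rp, k = 5, seed = s)
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("chain comparison ranks discriminative chains first", {
  rois <- separableRoiSet(n = 15, seed = 4)
  chains <- list(algorithmChain("mean_intensity", "mlp", name = "mean+mlp"),
                 algorithmChain("mean_intensity", "dummy", name = "mean+dummy"))
  rep_ <- compareChains(chains, rois, k = 5, seed = 2)
  expect_equal(rep_$chain[1], "mean+mlp")
  expect_gt(rep_$accuracy[1], rep_$accuracy[2])

  # identical chains listed twice give identical accuracies
  rep2 <- compareChains(list(chains[[1]], chains[[1]]), rois, k = 5, seed = 2)
  expect_equal(rep2$accuracy[1], rep2$accuracy[2])

  single <- compareChains(chains[1], rois, k = 5, seed = 2)
  expect_equal(nrow(single), 1L)
})

test_that("models serialize to JSON and back without changing predictions", {
  set.seed(7)
  X <- rbind(matrix(rnorm(30, 0), 15, 2), matrix(rnorm(30, 5), 15, 2))
  m <- trainMlp(X, rep(c(0, 1), each = 15), mlpConfig(seed = 3),
                chain = algorithmChain("haar3d", "mlp"))
  path <- withr::local_tempfile(fileext = ".json")
  writeModel(m, path)
  back <- readModel(path)
  expect_equal(predict(back, X)$score, predict(m, X)$score, tolerance = 1e-10)
  expect_equal(back@center, m@center, tolerance = 1e-12)

  # a restored model drives candidate classification through its stored chain
  m2 <- trainMlp(matrix(c(rnorm(10, 5), rnorm(10, 100)), 20, 1),
                 rep(c(0, 1), each = 10), mlpConfig(seed = 2),
                 chain = algorithmChain("mean_intensity", "mlp"))
  writeModel(m2, path)
  v <- makeBlobStack(data.frame(x = 8, y = 8, z = 3), peaks = 200,
                     dims = c(20, 20, 7))
  cand <- localMaxima(v, array(TRUE, dim = dim(stackData(v))), c(7, 7, 5))
  expect_equal(nMarkers(classifyCandidates(readModel(path), v, cand)),
               nMarkers(classifyCandidates(m2, v, cand)))
})
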