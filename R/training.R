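#' Training protocol configuration
#'
#' Training uses Adam with binary cross-entropy, batch size 64, and a
#' sample-size-dependent learning rate: datasets larger than
#' `largeDatasetThreshold` train at `learningRateLarge` (1e-5), smaller
#' ones at `learningRateSmall` (5e-5). Early stopping monitors validation
#' accuracy at threshold 0.5 and halts after `patience` consecutive epochs
#' without improvement; the returned model is the best-validation
#' checkpoint (earliest epoch on ties).
#'
#' @param batchSize Minibatch size (default 64).
#' @param learningRateSmall Adam learning rate for small datasets.
#' @param learningRateLarge Adam learning rate for large datasets.
#' @param largeDatasetThreshold Training-set size above which the large
#'   learning rate applies.
#' @param patience Consecutive non-improving epochs tolerated before
#'   stopping (default 30).
#' @param maxEpochs Hard epoch cap (default 500).
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed controlling fold assignment, weight
#'   initialization, shuffling and dropout.
#' @return A validated `TrainConfig` list.
#' @export
trainConfig <- function(batchSize = 64L, learningRateSmall = 5e-5,
                        learningRateLarge = 1e-5, largeDatasetThreshold = 40000L,
                        patience = 30L, maxEpochs = 500L, folds = 5L, seed = 1L) {
  if (learningRateSmall <= 0 || learningRateLarge <= 0)
    stopf("learning rates must be positive")
  patience <- as.integer(patience); maxEpochs <- as.integer(maxEpochs)
  if (patience >= maxEpochs) stopf("patience must be smaller than maxEpochs")
  if (as.integer(batchSize) < 1L) stopf("batchSize must be positive")
  if (as.integer(folds) < 2L) stopf("folds must be at least 2")
  structure(list(batchSize = as.integer(batchSize),
                 learningRateSmall = learningRateSmall,
                 learningRateLarge = learningRateLarge,
                 largeDatasetThreshold = as.integer(largeDatasetThreshold),
                 patience = patience, maxEpochs = maxEpochs,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "TrainConfig")
}

selectLearningRate <- function(trainCfg, nTrain) {
  if (nTrain > trainCfg$largeDatasetThreshold) trainCfg$learningRateLarge
  else trainCfg$learningRateSmall
}

#' Train one model on a train/validation split
#'
#' Runs minibatch Adam with per-epoch validation, early stopping on
#' validation accuracy, and best-checkpoint restoration. Fully
#' deterministic for a fixed `seed` (initialization, shuffling and dropout
#' all derive from it).
#'
#' @param trainWindows,valWindows Disjoint [MethylationWindows-class] sets.
#' @param modelCfg A [modelConfig()].
#' @param trainCfg A [trainConfig()].
#' @param seed Seed for this run; defaults to `trainCfg$seed`.
#' @param verbose Print per-epoch progress.
#' @return A list with `model` (best checkpoint), `log` (data frame with
#'   `epoch`, `train_loss`, `val_accuracy`, `best_so_far`), `bestEpoch`,
#'   `bestValAccuracy` and the learning rate used.
#' @export
trainFold <- function(trainWindows, valWindows, modelCfg, trainCfg = trainConfig(),
                      seed = trainCfg$seed, verbose = FALSE) {
  if (length(trainWindows) == 0L || length(valWindows) == 0L)
    stopf("training and validation sets must be nonempty")
  trainIdx <- encodeIndexMatrix(trainWindows)
  valIdx <- encodeIndexMatrix(valWindows)
  yTrain <- as.numeric(windowLabels(trainWindows))
  yVal <- as.integer(windowLabels(valWindows))
  lr <- selectLearningRate(trainCfg, nrow(trainIdx))

  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_accuracy = numeric(), best_so_far = numeric())
  bestAcc <- -Inf; bestTheta <- NULL; bestEpoch <- 0L; streak <- 0L
  model <- NULL

  withLocalSeed(seed, {
    model <- mambaModel(modelCfg, seed = sample.int(.Machine$integer.max - 1L, 1L))
    ptr <- liveHandle(model)
    n <- nrow(trainIdx)
    bs <- trainCfg$batchSize
    for (epoch in seq_len(trainCfg$maxEpochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0L
      for (s in seq(1L, n, bs)) {
        b <- ord[s:min(n, s + bs - 1L)]
        tot <- tot + net_train_batch(ptr, trainIdx[b, , drop = FALSE], yTrain[b],
                                     lr, 0.9, 0.999, 1e-8)
        nb <- nb + 1L
      }
      valScores <- predictScores(model, valIdx)
      acc <- mean((valScores > 0.5) == (yVal == 1L))
      if (acc > bestAcc) {
        bestAcc <- acc; bestEpoch <- epoch; streak <- 0L
        bestTheta <- as.numeric(net_get_theta(ptr))
      } else streak <- streak + 1L
      log[nrow(log) + 1L, ] <- list(epoch, tot / nb, acc, bestAcc)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val_acc %.4f  best %.4f",
                        epoch, tot / nb, acc, bestAcc))
      if (streak >= trainCfg$patience) break
    }
  })
  model <- setModelWeights(model, bestTheta)
  net_trim(liveHandle(model))
  list(model = model, log = log, bestEpoch = bestEpoch,
       bestValAccuracy = bestAcc, learningRate = lr)
}

#' Evaluate a model on a labeled dataset
#'
#' @param model A trained [MambaModel-class].
#' @param windows A [MethylationWindows-class] test set.
#' @param threshold Decision threshold for the label metrics.
#' @return A list with `scores`, `counts` and `metrics`
#'   (ACC/MCC/SN/SP/AUC).
#' @export
evaluateModel <- function(model, windows, threshold = 0.5) {
  scores <- predictScores(model, windows)
  y <- windowLabels(windows)
  counts <- confusionCounts(scores, y, threshold)
  m <- computeMetrics(counts)
  list(scores = scores, counts = counts,
       metrics = c(m, AUC = computeAuc(scores, y)))
}

#' Cross-validated training and test evaluation
#'
#' Splits the training set into `trainCfg$folds` stratified folds, trains
#' one model per fold with [trainFold()] (validating on the held-out fold),
#' evaluates every fold model on the independent test set, and reports
#' per-fold metrics with mean and standard deviation. The number of
#' sequences shared between training and test data is checked and recorded
#' in the report.
#'
#' @param trainWindows Training [MethylationWindows-class].
#' @param testWindows Independent test [MethylationWindows-class].
#' @param modelCfg A [modelConfig()].
#' @param trainCfg A [trainConfig()].
#' @param keepModels Keep the per-fold models in the report (memory-heavy
#'   for the default architecture).
#' @param ensemble Additionally report the score-averaged ensemble of the
#'   fold models as row `"ensemble"` in the summary.
#' @param verbose Print progress.
#' @return A [MetricsReport-class].
#' @export
crossValidate <- function(trainWindows, testWindows, modelCfg,
                          trainCfg = trainConfig(), keepModels = FALSE,
                          ensemble = FALSE, verbose = FALSE) {
  folds <- kfoldSplit(trainWindows, trainCfg$folds, trainCfg$seed)
  foldSeeds <- withLocalSeed(trainCfg$seed,
                             sample.int(.Machine$integer.max - 1L, length(folds)))
  overlap <- length(intersect(as.character(windowSequences(trainWindows)),
                              as.character(windowSequences(testWindows))))
  rows <- list(); logs <- list(); models <- list(); scoreMat <- NULL
  for (f in seq_along(folds)) {
    if (verbose) message("fold ", f, "/", length(folds))
    fit <- trainFold(trainWindows[folds[[f]]$train], trainWindows[folds[[f]]$val],
                     modelCfg, trainCfg, seed = foldSeeds[f], verbose = verbose)
    ev <- evaluateModel(fit$model, testWindows)
    rows[[f]] <- data.frame(fold = f, t(ev$metrics))
    logs[[f]] <- fit$log
    scoreMat <- cbind(scoreMat, ev$scores)
    if (keepModels) models[[f]] <- fit$model
  }
  perFold <- do.call(rbind, rows)
  mcols <- setdiff(names(perFold), "fold")
  summ <- rbind(mean = colMeans(perFold[mcols]),
                sd = apply(perFold[mcols], 2, sd))
  summ <- data.frame(statistic = rownames(summ), summ, row.names = NULL)
  if (ensemble) {
    ens <- rowMeans(scoreMat)
    y <- windowLabels(testWindows)
    em <- c(computeMetrics(confusionCounts(ens, y)), AUC = computeAuc(ens, y))
    summ <- rbind(summ, data.frame(statistic = "ensemble", t(em)))
  }
  new("MetricsReport", perFold = perFold, summary = summ, logs = logs,
      models = models,
      info = list(foldSeeds = foldSeeds, overlapWithTest = overlap))
}
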