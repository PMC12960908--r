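test_that("training configuration is validated", {
  expect_error(trainConfig(patience = 10, maxEpochs = 10), "smaller")
  expect_error(trainConfig(learningRateSmall = 0), "positive")
  expect_error(trainConfig(folds = 1), "at least 2")
})

test_that("the learning rate follows the dataset-size rule", {
  w <- randomWindows(30, seed = 3)
  tc <- trainConfig(largeDatasetThreshold = 10, patience = 0, maxEpochs = 2,
                    seed = 1)
  fit <- trainFold(w[1:20], w[21:30], tinyModelConfig(windowLength = 41), tc)
  expect_equal(fit$learningRate, tc$learningRateLarge)
  tc2 <- trainConfig(largeDatasetThreshold = 1000, patience = 0, maxEpochs = 2,
                     seed = 1)
  fit2 <- trainFold(w[1:20], w[21:30], tinyModelConfig(windowLength = 41), tc2)
  expect_equal(fit2$learningRate, tc2$learningRateSmall)
})

test_that("patience zero stops after exactly one epoch", {
  w <- randomWindows(24, seed = 5)
  tc <- trainConfig(batchSize = 12, patience = 0, maxEpochs = 50, seed = 2)
  fit <- trainFold(w[1:16], w[17:24], tinyModelConfig(windowLength = 41), tc)
  expect_equal(nrow(fit$log), 1L)
  expect_equal(fit$bestEpoch, 1L)
})

test_that("a small model can overfit one batch to perfect training accuracy", {
  w <- simulateWindows(generatorConfig(
    nPerClass = 16, motif = motifSpec("GAG", 20, 1, 0), seed = 6))
  tc <- trainConfig(batchSize = 32, learningRateSmall = 2e-3,
                    patience = 149, maxEpochs = 150, seed = 3)
  fit <- trainFold(w, w, smallModelConfig(), tc)   # validate on the training data
  trainAcc <- mean((predictScores(fit$model, w) > 0.5) == (windowLabels(w) == 1))
  expect_equal(trainAcc, 1)
})

test_that("training is deterministic given a seed", {
  w <- randomWindows(40, seed = 7)
  tc <- trainConfig(batchSize = 16, patience = 2, maxEpochs = 3, seed = 11)
  f1 <- trainFold(w[1:30], w[31:40], tinyModelConfig(windowLength = 41), tc)
  f2 <- trainFold(w[1:30], w[31:40], tinyModelConfig(windowLength = 41), tc)
  expect_identical(f1$log, f2$log)
  expect_identical(modelWeights(f1$model), modelWeights(f2$model))
  f3 <- trainFold(w[1:30], w[31:40], tinyModelConfig(windowLength = 41),
                  trainConfig(batchSize = 16, patience = 2, maxEpochs = 3,
                              seed = 12))
  expect_false(identical(f1$log$train_loss, f3$log$train_loss))
})

test_that("shrinking patience never increases the epochs trained", {
  w <- randomWindows(40, seed = 9)
  epochsFor <- function(p) {
    tc <- trainConfig(batchSize = 20, patience = p, maxEpochs = 8, seed = 4)
    nrow(trainFold(w[1:30], w[31:40], tinyModelConfig(windowLength = 41), tc)$log)
  }
  e <- vapply(c(0, 1, 3), epochsFor, 0)
  expect_true(all(diff(e) >= 0))
})

test_that("cross-validation aggregates fold metrics over a disjoint test set", {
  train <- simulateWindows(generatorConfig(
    nPerClass = 40, motif = motifSpec("GAG", 20, 1, 0), seed = 13))
  test <- simulateWindows(generatorConfig(
    nPerClass = 20, motif = motifSpec("GAG", 20, 1, 0), seed = 14))
  tc <- trainConfig(batchSize = 20, patience = 1, maxEpochs = 2, folds = 2,
                    seed = 5)
  rep <- crossValidate(train, test, tinyModelConfig(windowLength = 41), tc,
                       ensemble = TRUE)
  pf <- perFoldMetrics(rep)
  expect_equal(nrow(pf), 2L)
  sm <- summaryMetrics(rep)
  expect_equal(sm$MCC[sm$statistic == "mean"], mean(pf$MCC))
  expect_equal(sm$ACC[sm$statistic == "mean"], mean(pf$ACC))
  expect_true("ensemble" %in% sm$statistic)
  expect_equal(rep@info$overlapWithTest, 0L)
  expect_length(rep@logs, 2L)
})

test_that("ablation tables are deterministic and deltas reference the baseline", {
  train <- simulateWindows(generatorConfig(
    nPerClass = 30, motif = motifSpec("GAG", 20, 1, 0), seed = 15))
  test <- simulateWindows(generatorConfig(
    nPerClass = 15, motif = motifSpec("GAG", 20, 1, 0), seed = 16))
  tc <- trainConfig(batchSize = 20, patience = 0, maxEpochs = 1, folds = 2,
                    seed = 6)
  cfg <- tinyModelConfig(windowLength = 41)

  one <- runAblation(train, test, cfg, tc,
                     variants = list(only = list(convMode = "position_specific",
                                                 windowSizes = c(3L, 5L))))
  expect_equal(nrow(one$summary), 1L)
  expect_equal(one$summary$dMCC, 0)

  twice <- runAblation(train, test, cfg, tc,
                       variants = list(a = list(convMode = "shared"),
                                       b = list(convMode = "shared")))
  a <- twice$table[twice$table$variant == "a", -1]
  b <- twice$table[twice$table$variant == "b", -1]
  expect_equal(a, b, ignore_attr = TRUE)     # same seed, same variant -> same rows
})
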