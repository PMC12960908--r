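test_that("model configuration is validated", {
  expect_error(modelConfig(windowLength = 40), "odd")
  expect_error(modelConfig(windowSizes = c(3, 4)), "odd")
  expect_error(modelConfig(windowSizes = 43), "larger")
  expect_error(modelConfig(fcDims = c(64, 16, 2)), "ending in 1")
  expect_error(modelConfig(dropout = 1), "dropout")
})

test_that("zero layer weights leave the residual path as identity", {
  m <- mambaModel(tinyModelConfig(), seed = 2)
  m <- zeroWeightsExcept(m, keep = "emb")
  w <- randomWindows(3, L = 7, seed = 3)
  fw <- modelForward(m, w)
  lay <- weightLayout(m)
  embRow <- lay[lay$name == "emb", ]
  emb <- matrix(modelWeights(m)[embRow$offset:(embRow$offset + 4 * 4 - 1)], 4, 4)
  idx <- encodeWindows(w, 10)[[1]]$indices
  Xemb <- embedBatch(idx, emb)                 # windows x L x N
  for (b in seq_along(fw$Zk)) {
    for (t in 1:7)
      expect_equal(fw$Zk[[b]][, , t], Xemb[, t, ], tolerance = 1e-12)
  }
  # equal branches + zero queries fuse back to the embedding; zero head
  # gives sigmoid(0) = 0.5
  expect_equal(unname(fw$scores), rep(0.5, 3))
})

test_that("zero-depth branches are the identity and outputs keep their shape", {
  cfg <- tinyModelConfig()
  cfg$layers_per_block <- 0L
  m <- mambaModel(cfg, seed = 5)
  w <- randomWindows(4, L = 7, seed = 8)
  fw <- modelForward(m, w)
  expect_equal(dim(fw$Z), c(4, 4, 7))          # windows x N x L
  expect_equal(fw$Zk[[1]], fw$Zk[[3]])         # every branch is the embedding
  expect_equal(dim(fw$penultimate), c(4, 8))

  m2 <- mambaModel(tinyModelConfig(hiddenDim = 9, numFilters = 5, stateDim = 2),
                   seed = 5)
  fw2 <- modelForward(m2, w)
  expect_equal(dim(fw2$Z), c(4, 4, 7))         # independent of M, F, S
})

test_that("inference is deterministic and batch-equivariant", {
  m <- mambaModel(tinyModelConfig(dropout = 0.2), seed = 9)
  w <- randomWindows(6, L = 7, seed = 10)
  s1 <- predictScores(m, w)
  s2 <- predictScores(m, w)
  expect_identical(s1, s2)                     # dropout off at inference
  expect_true(all(s1 > 0 & s1 < 1))
  rev <- predictScores(m, w[6:1])
  expect_equal(unname(rev), unname(s1[6:1]))
  # identical sequences get identical scores
  w2 <- MethylationWindows(rep(as.character(windowSequences(w))[1], 2), c(1, 0))
  sDup <- predictScores(m, w2)
  expect_equal(sDup[[1]], sDup[[2]])
})

test_that("the score is strictly monotone in the final-layer bias", {
  m <- mambaModel(tinyModelConfig(), seed = 12)
  w <- randomWindows(2, L = 7, seed = 1)
  lay <- weightLayout(m)
  off <- lay$offset[lay$name == "b3"]
  th <- modelWeights(m)
  s0 <- predictScores(m, w)
  th[off] <- th[off] + 1
  s1 <- predictScores(setModelWeights(m, th), w)
  expect_true(all(s1 > s0))
})

test_that("shared mode uses exactly 1/L of the position-specific conv weights", {
  ps <- mambaModel(tinyModelConfig(), seed = 1)
  sh <- mambaModel(tinyModelConfig(convMode = "shared"), seed = 1)
  expect_equal(convParameterCount(ps), 7 * convParameterCount(sh))
  expect_equal(numParameters(ps) - convParameterCount(ps),
               numParameters(sh) - convParameterCount(sh))
})

test_that("analytic gradients match finite differences on a small setup", {
  cfg <- tinyModelConfig()
  m <- mambaModel(cfg, seed = 21)
  ptr <- ssm6mA:::liveHandle(m)
  set.seed(22)
  idx <- matrix(sample(0:3, 3 * 7, replace = TRUE), 3, 7)
  y <- c(1, 0, 1)
  ssm6mA:::net_loss_grad(ptr, idx, y, TRUE)
  g <- ssm6mA:::net_get_grad(ptr)
  th <- modelWeights(m)
  coords <- sample(length(th), 80)
  h <- 1e-5
  for (j in coords) {
    tp <- th; tp[j] <- tp[j] + h
    ssm6mA:::net_set_theta(ptr, tp)
    lp <- ssm6mA:::net_loss_grad(ptr, idx, y, TRUE)
    tm <- th; tm[j] <- tm[j] - h
    ssm6mA:::net_set_theta(ptr, tm)
    lm <- ssm6mA:::net_loss_grad(ptr, idx, y, TRUE)
    fd <- (lp - lm) / (2 * h)
    expect_lt(abs(g[j] - fd) / max(1e-6, abs(g[j]) + abs(fd)), 1e-3)
  }
})

test_that("checkpoints round-trip bit-identically", {
  fit <- trainedSmallFit()
  d <- tempfile()
  saveModel(fit$model, d)
  m2 <- loadModel(d)
  expect_identical(modelWeights(m2), modelWeights(fit$model))
  expect_identical(predictScores(m2, fit$val), predictScores(fit$model, fit$val))
  expect_error(loadModel(tempfile()), "checkpoint")
})

test_that("the fused intermediate agrees with the standalone fusion operation", {
  m <- mambaModel(tinyModelConfig(), seed = 30)
  w <- randomWindows(2, L = 7, seed = 31)
  fw <- modelForward(m, w)
  lay <- weightLayout(m)
  th <- modelWeights(m)
  qs <- lapply(c("Q3", "Q5", "Q7"), function(nm) {
    r <- lay[lay$name == nm, ]
    th[r$offset:(r$offset + r$nrow - 1)]
  })
  for (b in 1:2) {
    zs <- lapply(fw$Zk, function(z) t(z[b, , ]))   # L x N
    expect_equal(t(fw$Z[b, , ]), fuseScales(zs, qs)$Z, tolerance = 1e-12)
  }
})
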