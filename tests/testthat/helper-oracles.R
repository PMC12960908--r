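# Independent reference implementations used to check the package kernels.

# Direct nested-loop evaluation of the position-specific convolution:
# g[i,p] = sum_k sum_j f[i,p,k,j] * d[i - floor(K/2) + k - 1, j]
oracleConv <- function(D, bank) {
  L <- nrow(D); M <- ncol(D)
  F <- dim(bank)[2]; K <- dim(bank)[3]
  c0 <- K %/% 2
  G <- matrix(0, L, F)
  for (i in seq_len(L)) for (p in seq_len(F)) {
    acc <- 0
    for (k in seq_len(K)) for (j in seq_len(M)) {
      r <- i - c0 + k - 1
      if (r >= 1 && r <= L) acc <- acc + bank[i, p, k, j] * D[r, j]
    }
    G[i, p] <- acc
  }
  G
}

# Standard shared cross-correlation with zero padding (one filter bank for
# all positions); bank is F x K x M.
oracleSharedConv <- function(D, bank) {
  L <- nrow(D); M <- ncol(D)
  F <- dim(bank)[1]; K <- dim(bank)[2]
  c0 <- K %/% 2
  G <- matrix(0, L, F)
  for (i in seq_len(L)) for (p in seq_len(F)) {
    acc <- 0
    for (k in seq_len(K)) for (j in seq_len(M)) {
      r <- i - c0 + k - 1
      if (r >= 1 && r <= L) acc <- acc + bank[p, k, j] * D[r, j]
    }
    G[i, p] <- acc
  }
  G
}

# Naive step-by-step recurrence: h_t = Abar_t (.) h_{t-1} + Bbar_t g_{t,p},
# z_{t,p} = <C_t, h_t>, h_0 = 0.
oracleScan <- function(G, Abar, Bbar, C) {
  L <- nrow(G); F <- ncol(G); S <- ncol(Abar)
  Z <- matrix(0, L, F)
  for (p in seq_len(F)) {
    h <- numeric(S)
    for (t in seq_len(L)) {
      h <- Abar[t, ] * h + Bbar[t, ] * G[t, p]
      Z[t, p] <- sum(C[t, ] * h)
    }
  }
  Z
}

# Brute-force AUC: fraction of positive/negative pairs ordered correctly,
# ties counting one half.
oracleAuc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

tinyModelConfig <- function(windowLength = 7, embeddingDim = 4, hiddenDim = 6,
                            numFilters = 6, stateDim = 3, dropout = 0, ...) {
  modelConfig(windowLength = windowLength, embeddingDim = embeddingDim,
              hiddenDim = hiddenDim, numFilters = numFilters,
              stateDim = stateDim, windowSizes = c(3, 5, 7),
              layersPerBlock = 1, fcDims = c(16, 8, 1), dropout = dropout, ...)
}

smallModelConfig <- function(...) {
  modelConfig(windowLength = 41, embeddingDim = 8, hiddenDim = 16,
              numFilters = 16, stateDim = 4, windowSizes = c(3, 5, 7),
              layersPerBlock = 1, fcDims = c(64, 16, 1), dropout = 0.2, ...)
}

randomWindows <- function(n, L = 41, seed = 1) {
  simulateWindows(generatorConfig(
    nPerClass = ceiling(n / 2), windowLength = L,
    motif = motifSpec("A", (L + 1) %/% 2, 0, 0), seed = seed))[seq_len(n)]
}

# Zero every weight tensor except those named in `keep`.
zeroWeightsExcept <- function(model, keep = character()) {
  lay <- weightLayout(model)
  th <- modelWeights(model)
  for (i in seq_len(nrow(lay))) {
    if (lay$name[i] %in% keep) next
    n <- lay$nrow[i] * lay$ncol[i] * lay$nslice[i]
    th[lay$offset[i]:(lay$offset[i] + n - 1)] <- 0
  }
  setModelWeights(model, th)
}

# Memoized small trained model on an easy planted-motif task, shared by the
# interpretation and CLI tests.
.fixtures <- new.env(parent = emptyenv())

trainedSmallFit <- function() {
  if (!is.null(.fixtures$fit)) return(.fixtures$fit)
  train <- simulateWindows(generatorConfig(
    nPerClass = 250, motif = motifSpec("GAG", 20, 1, 0), seed = 31))
  val <- simulateWindows(generatorConfig(
    nPerClass = 80, motif = motifSpec("GAG", 20, 1, 0), seed = 32))
  tc <- trainConfig(batchSize = 50, learningRateSmall = 1e-3,
                    patience = 5, maxEpochs = 6, seed = 7)
  fit <- trainFold(train, val, smallModelConfig(), tc)
  fit$train <- train
  fit$val <- val
  .fixtures$fit <- fit
  fit
}
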