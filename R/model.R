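#' Model architecture configuration
#'
#' Defines the multi-scale selective state-space classifier. Each of the
#' `windowSizes` gets its own branch of `layersPerBlock` stacked layers; a
#' layer projects the `N`-dimensional embedding to hidden width `M`, applies
#' a position-specific (or shared) linear filter bank of `F` filters with
#' the branch's window size, runs the SiLU-activated output through an
#' input-dependent state-space recurrence with `S` states per channel,
#' layer-normalizes, projects back to `N` and adds the residual. Branch
#' outputs are fused by per-cell softmax weights derived from learnable
#' query vectors, flattened, and classified by fully connected layers of
#' widths `fcDims` (ReLU + dropout after the first two, sigmoid output).
#'
#' `N`, `M`, `F` and `S` are implementation defaults chosen so the flattened
#' fused matrix (41 x 32 = 1312 values) feeds the 384-wide first classifier
#' layer comfortably; all are configurable.
#'
#' @param windowLength Odd sequence window length `L` (default 41).
#' @param embeddingDim Embedding/output feature dimension `N` (default 32).
#' @param hiddenDim Branch hidden width `M` (default 64).
#' @param numFilters Filters `F` in the positional filter bank (default `M`).
#' @param stateDim State dimension `S` of the recurrence (default 16).
#' @param windowSizes Odd filter window sizes, one branch each (default 3,5,7).
#' @param layersPerBlock Stacked layers per branch (default 6).
#' @param fcDims Classifier widths, last must be 1 (default 384, 16, 1).
#' @param dropout Dropout rate in the classifier head (default 0.2).
#' @param convMode `"position_specific"` (every position has its own filter
#'   weights) or `"shared"` (one filter bank for all positions).
#' @return A validated `ModelConfig` list with fields `L`, `N`, `M`, `F`,
#'   `S`, `windows`, `layers_per_block`, `fc_dims`, `dropout`, `conv_mode`.
#' @export
modelConfig <- function(windowLength = 41L, embeddingDim = 32L, hiddenDim = 64L,
                        numFilters = hiddenDim, stateDim = 16L,
                        windowSizes = c(3L, 5L, 7L), layersPerBlock = 6L,
                        fcDims = c(384L, 16L, 1L), dropout = 0.2,
                        convMode = c("position_specific", "shared")) {
  convMode <- match.arg(convMode)
  L <- as.integer(windowLength)
  ws <- as.integer(windowSizes)
  fc <- as.integer(fcDims)
  if (L < 1L || L %% 2L == 0L) stopf("windowLength must be a positive odd integer")
  if (length(ws) < 1L || any(ws %% 2L == 0L) || any(ws > L))
    stopf("window sizes must be odd and no larger than the window length")
  if (length(fc) != 3L || fc[3] != 1L)
    stopf("fcDims must be three widths ending in 1")
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  if (as.integer(layersPerBlock) < 0L) stopf("layersPerBlock must be >= 0")
  structure(list(L = L, N = as.integer(embeddingDim), M = as.integer(hiddenDim),
                 F = as.integer(numFilters), S = as.integer(stateDim),
                 windows = ws, layers_per_block = as.integer(layersPerBlock),
                 fc_dims = fc, dropout = as.numeric(dropout), conv_mode = convMode),
            class = "ModelConfig")
}

# Fan-in scaled uniform initialization for affine maps; embedding rows
# N(0, 1/N); state matrix A = -exp(A_log) initialized to -(1..S);
# step-size bias set so softplus gives 0.1 at zero input.
initialWeights <- function(ptr, seed) {
  lay <- net_layout(ptr)
  th <- numeric(net_nparam(ptr))
  withLocalSeed(seed, {
    for (i in seq_len(nrow(lay))) {
      nm <- sub(".*\\.", "", lay$name[i])
      n <- lay$nrow[i] * lay$ncol[i] * lay$nslice[i]
      vals <-
        if (nm == "emb") rnorm(n) / sqrt(lay$ncol[i])
        else if (nm == "A_log") rep_len(log(seq_len(lay$nrow[i])), n)
        else if (nm == "b_dt") log(expm1(0.1))
        else if (nm == "ln_g") rep(1, n)
        else if (startsWith(nm, "b_") || nm == "ln_b") rep(0, n)
        else runif(n, -1, 1) / sqrt(lay$nrow[i])
      th[lay$offset[i]:(lay$offset[i] + n - 1)] <- vals
    }
  })
  th
}

#' Create a model with freshly initialized weights
#'
#' @param config A [modelConfig()].
#' @param seed Integer seed for weight initialization.
#' @return A [MambaModel-class] object.
#' @examples
#' m <- mambaModel(modelConfig(windowLength = 7, embeddingDim = 4, hiddenDim = 6,
#'                             stateDim = 2, windowSizes = 3, layersPerBlock = 1,
#'                             fcDims = c(8, 4, 1)), seed = 1)
#' numParameters(m)
#' @export
mambaModel <- function(config, seed = 1L) {
  if (!inherits(config, "ModelConfig")) stopf("config must come from modelConfig()")
  ptr <- net_create(config)
  th <- initialWeights(ptr, seed)
  net_set_theta(ptr, th)
  new("MambaModel", config = unclass(config), ptr = ptr, weights = th)
}

# Return a live native handle, rebuilding it from the weight mirror if the
# external pointer went stale (e.g. the object came back through readRDS).
liveHandle <- function(model) {
  if (!net_is_valid(model@ptr)) {
    ptr <- net_create(model@config)
    net_set_theta(ptr, model@weights)
    return(ptr)
  }
  model@ptr
}

#' Number of trainable parameters
#' @param model A [MambaModel-class].
#' @return Parameter count.
#' @export
numParameters <- function(model) {
  as.numeric(net_nparam(liveHandle(model)))
}

#' Parameter count of the convolutional front-end
#'
#' Counts only the positional filter-bank weights, which is where the
#' position-specific and shared modes differ (by exactly a factor of `L`).
#'
#' @param model A [MambaModel-class].
#' @return Total number of filter-bank weights.
#' @export
convParameterCount <- function(model) {
  lay <- net_layout(liveHandle(model))
  sel <- grepl("\\.Wc$", lay$name)
  sum(lay$nrow[sel] * lay$ncol[sel] * lay$nslice[sel])
}

#' Get or set model weights
#'
#' @param model A [MambaModel-class].
#' @return `modelWeights` returns the flat numeric weight vector;
#'   `setModelWeights` returns the model with updated weights.
#' @export
modelWeights <- function(model) {
  as.numeric(net_get_theta(liveHandle(model)))
}

#' @rdname modelWeights
#' @param weights Numeric vector as returned by `modelWeights`.
#' @export
setModelWeights <- function(model, weights) {
  ptr <- liveHandle(model)
  net_set_theta(ptr, as.numeric(weights))
  new("MambaModel", config = model@config, ptr = ptr,
      weights = as.numeric(weights))
}

#' Named layout of the weight vector
#'
#' @param model A [MambaModel-class].
#' @return Data frame with one row per parameter tensor: `name`, 1-based
#'   `offset` into the weight vector, and `nrow`/`ncol`/`nslice` dimensions.
#' @export
weightLayout <- function(model) net_layout(liveHandle(model))

asIndexMatrix <- function(x) {
  if (is(x, "MethylationWindows")) encodeIndexMatrix(x)
  else if (is.list(x) && !is.null(x$indices)) x$indices
  else if (is.matrix(x)) x
  else stopf("expected MethylationWindows, an encoded batch, or an index matrix")
}

#' Predict 6mA scores
#'
#' Runs the model in inference mode (dropout off); deterministic for fixed
#' weights.
#'
#' @param model A [MambaModel-class].
#' @param x A [MethylationWindows-class] object, an encoded batch, or an
#'   integer index matrix.
#' @param chunkSize Windows per forward pass.
#' @return Numeric vector of scores in (0,1), named by window id when ids
#'   are available.
#' @export
predictScores <- function(model, x, chunkSize = 64L) {
  idx <- asIndexMatrix(x)
  ptr <- liveHandle(model)
  n <- nrow(idx)
  out <- numeric(n)
  for (s in seq(1L, n, chunkSize)) {
    e <- min(n, s + chunkSize - 1L)
    out[s:e] <- net_forward(ptr, idx[s:e, , drop = FALSE], FALSE)$scores
  }
  names(out) <- rownames(idx)
  out
}

#' Full forward pass with intermediates
#'
#' In addition to the scores, returns the fused feature matrix `Z` (used by
#' [featureIntensity()]), the per-branch outputs, and the penultimate
#' classifier activations (used by [extractPenultimate()]).
#'
#' @inheritParams predictScores
#' @return A list with `scores`, `penultimate` (windows x width-16 matrix),
#'   `Z` (array windows x N x L) and `Zk` (list of per-branch arrays).
#' @export
modelForward <- function(model, x, chunkSize = 64L) {
  idx <- asIndexMatrix(x)
  ptr <- liveHandle(model)
  n <- nrow(idx)
  pieces <- lapply(seq(1L, n, chunkSize), function(s) {
    e <- min(n, s + chunkSize - 1L)
    net_forward(ptr, idx[s:e, , drop = FALSE], TRUE)
  })
  nb <- length(model@config$windows)
  list(scores = setNames(unlist(lapply(pieces, `[[`, "scores")), rownames(idx)),
       penultimate = do.call(rbind, lapply(pieces, `[[`, "penultimate")),
       Z = abindRows(lapply(pieces, `[[`, "Z")),
       Zk = lapply(seq_len(nb), function(b)
         abindRows(lapply(pieces, function(p) p$Zk[[b]]))))
}

# bind 3-d arrays along the first (window) dimension
abindRows <- function(arrs) {
  if (length(arrs) == 1L) return(arrs[[1]])
  d <- dim(arrs[[1]])
  out <- array(0, c(sum(vapply(arrs, function(a) dim(a)[1], 0)), d[2], d[3]))
  at <- 1L
  for (a in arrs) {
    out[at:(at + dim(a)[1] - 1L), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Save or load a model checkpoint
#'
#' A checkpoint directory holds the configuration as plain-text YAML and the
#' weight vector in R's native serialization. `loadModel(saveModel(m, d))`
#' reproduces forward passes bit-identically.
#'
#' @param model A [MambaModel-class].
#' @param dir Checkpoint directory.
#' @return `saveModel` returns `dir` invisibly; `loadModel` returns the
#'   restored [MambaModel-class].
#' @export
saveModel <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  yaml::write_yaml(model@config, file.path(dir, "model_config.yaml"))
  saveRDS(modelWeights(model), file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  cfgPath <- file.path(dir, "model_config.yaml")
  wPath <- file.path(dir, "weights.rds")
  if (!file.exists(cfgPath) || !file.exists(wPath))
    stopf("'%s' is not a model checkpoint directory", dir)
  cfg <- yaml::read_yaml(cfgPath)
  cfg$windows <- as.integer(cfg$windows)
  cfg$fc_dims <- as.integer(cfg$fc_dims)
  for (f in c("L", "N", "M", "F", "S", "layers_per_block"))
    cfg[[f]] <- as.integer(cfg[[f]])
  ptr <- net_create(cfg)
  th <- readRDS(wPath)
  net_set_theta(ptr, th)
  new("MambaModel", config = cfg, ptr = ptr, weights = th)
}
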