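#' Build an ablation variant list
#'
#' Variants combine a convolution mode (position-specific vs shared
#' filters) with a set of branch window sizes (any of the single scales 3,
#' 5, 7 or their combinations).
#'
#' @param convModes Character vector of conv modes to include.
#' @param windowSets List of integer vectors of window sizes.
#' @return Named list of variants usable with [runAblation()].
#' @export
ablationVariants <- function(convModes = c("position_specific", "shared"),
                             windowSets = list(c(3L, 5L, 7L))) {
  out <- list()
  for (cm in convModes)
    for (wset in windowSets) {
      nm <- paste0(if (cm == "shared") "shared" else "pos", "_",
                   paste(wset, collapse = ""))
      out[[nm]] <- list(convMode = cm, windowSizes = as.integer(wset))
    }
  out
}

#' Run an ablation comparison
#'
#' Trains and evaluates each variant with [crossValidate()] under identical
#' fold splits and seeds (only the architecture flags change), then tables
#' per-fold ACC/MCC/SN/SP/AUC and per-variant means with deltas against a
#' named baseline variant.
#'
#' @param trainWindows,testWindows Train and independent test
#'   [MethylationWindows-class] sets.
#' @param modelCfg Base [modelConfig()]; each variant overrides its
#'   `convMode` and `windowSizes`.
#' @param trainCfg A [trainConfig()].
#' @param variants Named list from [ablationVariants()] (or built by hand:
#'   each element needs `convMode` and `windowSizes`).
#' @param baseline Name of the variant used as delta reference (default:
#'   first variant).
#' @param verbose Print progress.
#' @return A list of class `AblationResult` with `table` (per variant and
#'   fold) and `summary` (per-variant means plus `dACC`/`dMCC`/`dAUC`
#'   deltas against the baseline).
#' @export
runAblation <- function(trainWindows, testWindows, modelCfg,
                        trainCfg = trainConfig(), variants = ablationVariants(),
                        baseline = names(variants)[1], verbose = FALSE) {
  if (is.null(names(variants)) || any(!nzchar(names(variants))))
    stopf("variants must be a named list")
  if (!baseline %in% names(variants))
    stopf("baseline '%s' is not among the variants", baseline)
  tabs <- list()
  for (nm in names(variants)) {
    v <- variants[[nm]]
    cfg <- modelConfig(
      windowLength = modelCfg$L, embeddingDim = modelCfg$N,
      hiddenDim = modelCfg$M, numFilters = modelCfg$F, stateDim = modelCfg$S,
      windowSizes = v$windowSizes %||% modelCfg$windows,
      layersPerBlock = modelCfg$layers_per_block, fcDims = modelCfg$fc_dims,
      dropout = modelCfg$dropout, convMode = v$convMode %||% modelCfg$conv_mode)
    if (verbose) message("variant ", nm)
    rep <- crossValidate(trainWindows, testWindows, cfg, trainCfg,
                         verbose = verbose)
    tabs[[nm]] <- data.frame(variant = nm, perFoldMetrics(rep))
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  mcols <- c("ACC", "MCC", "SN", "SP", "AUC")
  summary <- do.call(rbind, lapply(names(variants), function(nm) {
    data.frame(variant = nm, t(colMeans(table[table$variant == nm, mcols])))
  }))
  base <- summary[summary$variant == baseline, ]
  summary$dACC <- summary$ACC - base$ACC
  summary$dMCC <- summary$MCC - base$MCC
  summary$dAUC <- summary$AUC - base$AUC
  structure(list(table = table, summary = summary, baseline = baseline),
            class = "AblationResult")
}

#' @export
print.AblationResult <- function(x, ...) {
  cat("Ablation against baseline '", x$baseline, "':\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write ablation tables as TSV
#'
#' @param result An `AblationResult` from [runAblation()].
#' @param path Output TSV path (per-fold table); the summary goes to
#'   `<path>.summary.tsv`.
#' @return `path`, invisibly.
#' @export
writeAblationTsv <- function(result, path) {
  writeTsv(result$table, path)
  writeTsv(result$summary, paste0(path, ".summary.tsv"))
  invisible(path)
}
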