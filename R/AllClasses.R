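#' Labeled 6mA sequence windows
#'
#' Container for a set of fixed-length DNA windows centred on an adenine,
#' each labeled as 6mA-positive (1) or negative (0). All windows must have
#' the same odd length, contain only A/C/G/T, and carry A at the centre
#' position (1-based position `(L+1)/2`; 21 for the default 41-mers).
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width windows.
#' @slot labels Integer vector of 0/1 labels, one per window.
#' @slot speciesTag Single character string naming the dataset.
#'
#' @seealso [buildWindowSet()], [simulateWindows()]
#' @export
setClass("MethylationWindows",
  representation(seqs = "DNAStringSet", labels = "integer", speciesTag = "character"))

setValidity("MethylationWindows", function(object) {
  n <- length(object@seqs)
  if (length(object@labels) != n)
    return("labels and sequences differ in length")
  if (n == 0L) return(TRUE)
  if (!all(object@labels %in% c(0L, 1L)))
    return("labels must be 0 or 1")
  w <- Biostrings::width(object@seqs)
  if (length(unique(w)) != 1L)
    return("all windows must have the same length")
  L <- w[1]
  if (L %% 2L == 0L)
    return("window length must be odd")
  af <- Biostrings::alphabetFrequency(object@seqs, baseOnly = TRUE)
  bad <- which(af[, "other"] > 0)
  if (length(bad))
    return(sprintf("window '%s' contains characters outside A/C/G/T",
                   names(object@seqs)[bad[1]] %||% bad[1]))
  ctr <- as.character(Biostrings::subseq(object@seqs, (L + 1L) %/% 2L, (L + 1L) %/% 2L))
  if (any(ctr != "A")) {
    i <- which(ctr != "A")[1]
    return(sprintf("window '%s' does not have A at the centre position %d",
                   names(object@seqs)[i] %||% i, (L + 1L) %/% 2L))
  }
  TRUE
})

#' Construct a MethylationWindows object
#'
#' @param seqs A [Biostrings::DNAStringSet] or character vector of windows.
#' @param labels Numeric/integer vector of 0/1 labels.
#' @param speciesTag Dataset name carried through reports.
#' @return A [MethylationWindows-class] object.
#' @examples
#' w <- MethylationWindows(
#'   c(a = paste(rep("A", 41), collapse = ""), b = paste(rep("A", 41), collapse = "")),
#'   c(1, 0), "toy")
#' windowLength(w)
#' @export
MethylationWindows <- function(seqs, labels, speciesTag = "") {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  new("MethylationWindows", seqs = seqs, labels = as.integer(labels),
      speciesTag = as.character(speciesTag))
}

#' @describeIn MethylationWindows Window sequences as a DNAStringSet.
#' @param x,object A `MethylationWindows` object.
#' @export
windowSequences <- function(x) x@seqs

#' @describeIn MethylationWindows Integer 0/1 labels.
#' @export
windowLabels <- function(x) x@labels

#' @describeIn MethylationWindows Dataset tag.
#' @export
speciesTag <- function(x) x@speciesTag

#' @describeIn MethylationWindows Common window length (integer).
#' @export
windowLength <- function(x) {
  if (length(x@seqs) == 0L) return(NA_integer_)
  Biostrings::width(x@seqs)[1]
}

#' @describeIn MethylationWindows Counts of positive and negative windows.
#' @export
classCounts <- function(x) {
  c(positive = sum(x@labels == 1L), negative = sum(x@labels == 0L))
}

setMethod("length", "MethylationWindows", function(x) length(x@seqs))

setMethod("[", "MethylationWindows", function(x, i, j, ..., drop = TRUE) {
  initialize(x, seqs = x@seqs[i], labels = x@labels[i])
})

setMethod("show", "MethylationWindows", function(object) {
  cc <- classCounts(object)
  cat(sprintf("MethylationWindows: %d windows of length %s (%d positive, %d negative)\n",
              length(object), windowLength(object), cc[["positive"]], cc[["negative"]]))
  if (nzchar(object@speciesTag)) cat("  dataset:", object@speciesTag, "\n")
})

#' Fitted multi-scale selective state-space model
#'
#' Holds the model configuration and a handle to the native network object.
#' The handle is session-local reference semantics: training functions update
#' the weights in place. Use [saveModel()]/[loadModel()] to persist a model
#' across sessions; a `MambaModel` restored by `readRDS()` alone has a stale
#' handle and is rebuilt from its `weights` slot on first use.
#'
#' @slot config A model configuration from [modelConfig()].
#' @slot ptr External pointer to the native network.
#' @slot weights Numeric weight vector mirror used to rebuild stale handles.
#' @seealso [mambaModel()], [predictScores()], [trainFold()]
#' @export
setClass("MambaModel",
  representation(config = "list", ptr = "externalptr", weights = "numeric"))

setMethod("show", "MambaModel", function(object) {
  cfg <- object@config
  cat(sprintf("MambaModel: L=%d N=%d M=%d F=%d S=%d, %d layer(s)/block, windows {%s}, %s conv\n",
              cfg$L, cfg$N, cfg$M, cfg$F, cfg$S, cfg$layers_per_block,
              paste(cfg$windows, collapse = ","), cfg$conv_mode))
  cat(sprintf("  %s trainable parameters\n",
              format(numParameters(object), big.mark = ",")))
})

#' Cross-validation metrics report
#'
#' Per-fold test-set metrics (ACC, MCC, SN, SP, AUC) with mean/sd summary,
#' per-fold training logs, and bookkeeping about the folds.
#'
#' @slot perFold Data frame with one row per fold.
#' @slot summary Data frame with `mean` and `sd` rows.
#' @slot logs List of per-fold training logs.
#' @slot models List of per-fold [MambaModel-class] objects (empty unless
#'   `keepModels = TRUE` was passed to [crossValidate()]).
#' @slot info List with fold seeds and the train/test overlap count.
#' @export
setClass("MetricsReport",
  representation(perFold = "data.frame", summary = "data.frame",
                 logs = "list", models = "list", info = "list"))

#' @describeIn MetricsReport Per-fold metric rows.
#' @param x,object A `MetricsReport`.
#' @export
perFoldMetrics <- function(x) x@perFold

#' @describeIn MetricsReport Mean/sd summary rows.
#' @export
summaryMetrics <- function(x) x@summary

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", nrow(object@perFold), "fold(s)\n")
  print(object@perFold, digits = 4)
  cat("summary:\n")
  print(object@summary, digits = 4)
  if (!is.null(object@info$overlapWithTest))
    cat("train/test overlapping sequences:", object@info$overlapWithTest, "\n")
})
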