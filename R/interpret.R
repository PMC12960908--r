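#' Position-wise feature-intensity profile
#'
#' Extracts the fused feature matrix `Z` (positions x features) for every
#' window, averages over the feature dimension to get one intensity value
#' per position, and averages those vectors separately over the true
#' positive and true negative windows. On planted-motif data the
#' positive-minus-negative contrast localizes around the motif.
#'
#' @param model A trained [MambaModel-class].
#' @param windows A labeled [MethylationWindows-class] with both classes
#'   present.
#' @return Data frame with `position` (1-based), `meanPositive`,
#'   `meanNegative` and `contrast` (positive minus negative).
#' @export
featureIntensity <- function(model, windows) {
  y <- windowLabels(windows)
  if (!any(y == 1L) || !any(y == 0L))
    stopf("feature intensity needs both classes present")
  fw <- modelForward(model, windows)
  perWindow <- apply(fw$Z, c(1, 3), mean)      # windows x L
  data.frame(position = seq_len(ncol(perWindow)),
             meanPositive = colMeans(perWindow[y == 1L, , drop = FALSE]),
             meanNegative = colMeans(perWindow[y == 0L, , drop = FALSE]),
             contrast = colMeans(perWindow[y == 1L, , drop = FALSE]) -
                        colMeans(perWindow[y == 0L, , drop = FALSE]))
}

#' Penultimate-layer embeddings
#'
#' Returns the activations after the width-16 classifier layer and its
#' rectifier (dropout off), one row per window — the representation used
#' for 2-D projections (e.g. UMAP, via any external implementation).
#'
#' @param model A trained [MambaModel-class].
#' @param windows A [MethylationWindows-class].
#' @return Data frame with `id`, `label` and columns `v1..vK` (K = width of
#'   the penultimate layer).
#' @export
extractPenultimate <- function(model, windows) {
  fw <- modelForward(model, windows)
  emb <- fw$penultimate
  colnames(emb) <- paste0("v", seq_len(ncol(emb)))
  data.frame(id = names(windowSequences(windows)) %||%
               as.character(seq_len(length(windows))),
             label = windowLabels(windows), emb)
}

#' Per-position nucleotide enrichment
#'
#' Class-conditional base frequencies per position with a pseudocount of
#' 0.5 per cell, scored as `log2(freqPositive / freqNegative)`. This is a
#' simple log-odds summary of positional composition, not the
#' binomial-probability statistic of sequence-logo tools such as pLogo.
#'
#' @param windows A labeled [MethylationWindows-class] with both classes.
#' @return Data frame with `position`, `base`, `freqPos`, `freqNeg`,
#'   `log2Odds`. Frequencies sum to 1 over the four bases at every
#'   position within each class.
#' @export
positionEnrichment <- function(windows) {
  y <- windowLabels(windows)
  if (!any(y == 1L) || !any(y == 0L))
    stopf("enrichment needs both classes present")
  m <- as.matrix(windowSequences(windows))
  L <- ncol(m)
  bases <- c("A", "C", "G", "T")
  freq <- function(sub) {
    n <- nrow(sub)
    t(vapply(bases, function(b) (colSums(sub == b) + 0.5) / (n + 2), numeric(L)))
  }
  fp <- freq(m[y == 1L, , drop = FALSE])   # 4 x L
  fn <- freq(m[y == 0L, , drop = FALSE])
  data.frame(position = rep(seq_len(L), each = 4L),
             base = rep(bases, L),
             freqPos = as.vector(fp),
             freqNeg = as.vector(fn),
             log2Odds = as.vector(log2(fp / fn)))
}

#' Write interpretation outputs as TSV files
#'
#' Writes the intensity profile, enrichment table and penultimate
#' embeddings for a trained model and dataset.
#'
#' @param model A trained [MambaModel-class].
#' @param windows A labeled [MethylationWindows-class].
#' @param dir Output directory.
#' @return Named vector of file paths, invisibly.
#' @export
writeInterpretation <- function(model, windows, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "intensity_profile.tsv")
  p2 <- file.path(dir, "position_enrichment.tsv")
  p3 <- file.path(dir, "penultimate_embedding.tsv")
  writeTsv(featureIntensity(model, windows), p1)
  writeTsv(positionEnrichment(windows), p2)
  writeTsv(extractPenultimate(model, windows), p3)
  invisible(c(intensity = p1, enrichment = p2, embedding = p3))
}
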