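#' Read a FASTA file of DNA windows
#'
#' Reads FASTA records in file order, concatenating wrapped sequence lines
#' and upper-casing the bases. Records may contain only A/C/G/T/N (any
#' case); anything else raises an error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (possibly of length zero).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "AC", "GT"), f)
#' as.character(readFastaWindows(f))
#' @export
readFastaWindows <- function(path) {
  if (!file.exists(path)) stopf("FASTA file '%s' does not exist", path)
  seqs <- Biostrings::readBStringSet(path)
  up <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", up)
  if (any(bad))
    stopf("record '%s' contains characters outside {A,C,G,T,N}",
          names(seqs)[which(bad)[1]])
  out <- Biostrings::DNAStringSet(up)
  names(out) <- names(seqs)
  out
}

#' Write DNA windows to a FASTA file
#'
#' Writes one header and one sequence line per record, which makes output
#' byte-reproducible.
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFastaWindows <- function(seqs, path) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  s <- as.character(seqs)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(rbind(paste0(">", ids), s), con, sep = "\n")
  invisible(path)
}

#' Assemble a labeled dataset from paired class FASTA files
#'
#' Builds a [MethylationWindows-class] dataset in the benchmark layout: one
#' FASTA file of positive (6mA) windows and one of negative windows, labels
#' carried by file membership. Every window is validated for length,
#' alphabet and the centre adenine; windows containing N are rejected and
#' counted in the error message. Unequal class sizes produce a warning, not
#' an error.
#'
#' @param posPath FASTA file of positive windows (label 1).
#' @param negPath FASTA file of negative windows (label 0).
#' @param windowLength Required odd window length (default 41).
#' @param speciesTag Dataset name for reports.
#' @return A [MethylationWindows-class] object ordered positives first.
#' @export
buildWindowSet <- function(posPath, negPath, windowLength = 41L, speciesTag = "") {
  windowLength <- as.integer(windowLength)
  if (windowLength %% 2L == 0L) stopf("windowLength must be odd")
  pos <- readFastaWindows(posPath)
  neg <- readFastaWindows(negPath)
  validateClass <- function(seqs, what) {
    if (length(seqs) == 0L) return(seqs)
    af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
    nN <- which(af[, "other"] > 0)
    if (length(nN))
      stopf("%d %s window(s) contain N (first: '%s'); windows must be A/C/G/T only",
            length(nN), what, names(seqs)[nN[1]])
    w <- Biostrings::width(seqs)
    if (any(w != windowLength))
      stopf("%s window '%s' violates length: expected %d, found %d",
            what, names(seqs)[which(w != windowLength)[1]],
            windowLength, w[which(w != windowLength)[1]])
    ctr <- as.character(Biostrings::subseq(seqs, (windowLength + 1L) %/% 2L,
                                           (windowLength + 1L) %/% 2L))
    if (any(ctr != "A"))
      stopf("%s window '%s' violates centre base: expected A at position %d",
            what, names(seqs)[which(ctr != "A")[1]], (windowLength + 1L) %/% 2L)
    seqs
  }
  pos <- validateClass(pos, "positive")
  neg <- validateClass(neg, "negative")
  if (length(pos) != length(neg))
    warning(sprintf("unbalanced classes: %d positive vs %d negative windows",
                    length(pos), length(neg)))
  names(pos) <- make.unique(names(pos), sep = "_")
  names(neg) <- make.unique(names(neg), sep = "_")
  MethylationWindows(c(pos, neg),
                     c(rep(1L, length(pos)), rep(0L, length(neg))),
                     speciesTag)
}

#' Encode windows to integer index batches
#'
#' Maps bases to integer indices with the fixed encoding A=0, C=1, G=2, T=3
#' and splits the dataset into batches that preserve dataset order; the
#' final batch may be smaller.
#'
#' @param x A [MethylationWindows-class] object.
#' @param batchSize Positive integer batch size.
#' @return A list of batches; each batch is a list with `indices` (integer
#'   matrix, rows = windows), `labels` and `ids`.
#' @seealso [decodeBatch()]
#' @export
encodeWindows <- function(x, batchSize = 64L) {
  if (length(x) == 0L) stopf("cannot encode an empty dataset")
  batchSize <- as.integer(batchSize)
  if (batchSize < 1L) stopf("batchSize must be positive")
  idx <- encodeIndexMatrix(x)
  n <- nrow(idx)
  starts <- seq(1L, n, batchSize)
  lapply(starts, function(s) {
    e <- min(n, s + batchSize - 1L)
    list(indices = idx[s:e, , drop = FALSE],
         labels = x@labels[s:e],
         ids = rownames(idx)[s:e])
  })
}

# full dataset as one integer index matrix (rows named by window id)
encodeIndexMatrix <- function(x) {
  m <- as.matrix(x@seqs)
  idx <- matrix(match(m, c("A", "C", "G", "T")) - 1L, nrow = nrow(m))
  rownames(idx) <- names(x@seqs)
  storage.mode(idx) <- "integer"
  idx
}

#' Decode an encoded batch back to sequences
#'
#' @param batch A batch from [encodeWindows()], or a bare index matrix.
#' @return Character vector of sequences.
#' @export
decodeBatch <- function(batch) {
  idx <- if (is.list(batch)) batch$indices else batch
  chars <- c("A", "C", "G", "T")[idx + 1L]
  out <- apply(matrix(chars, nrow = nrow(idx)), 1, paste, collapse = "")
  names(out) <- rownames(idx)
  out
}

#' Stratified k-fold split
#'
#' Partitions dataset indices into `k` validation folds, stratified by label
#' so each fold's class ratio matches the dataset's within one window.
#' Deterministic for a given seed.
#'
#' @param x A [MethylationWindows-class] object or a 0/1 label vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer RNG seed.
#' @return A list of `k` elements, each `list(train = , val = )` of integer
#'   indices; the validation folds partition `seq_along(labels)`.
#' @export
kfoldSplit <- function(x, k = 5L, seed = 1L) {
  labels <- if (is(x, "MethylationWindows")) x@labels else as.integer(x)
  k <- as.integer(k)
  n <- length(labels)
  if (k < 2L) stopf("k must be at least 2")
  if (k > n) stopf("k = %d exceeds the dataset size %d", k, n)
  fold <- integer(n)
  withLocalSeed(seed, {
    for (lab in unique(labels)) {
      ii <- which(labels == lab)
      ii <- ii[sample.int(length(ii))]
      fold[ii] <- rep_len(seq_len(k), length(ii))
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), val = which(fold == f)))
}

#' Write per-window prediction scores as TSV
#'
#' @param ids Window identifiers.
#' @param scores Predicted probabilities in (0,1).
#' @param path Output TSV path.
#' @param threshold Decision threshold for the predicted label.
#' @return `path`, invisibly.
#' @export
writeScoresTsv <- function(ids, scores, path, threshold = 0.5) {
  writeTsv(data.frame(id = ids, score = scores,
                      predicted_label = as.integer(scores > threshold)), path)
}
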