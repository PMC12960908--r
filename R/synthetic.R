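#' Specify a planted motif
#'
#' Describes a short motif planted into simulated windows: the pattern, the
#' 1-based anchor of its first base, and the planting probabilities for the
#' two classes. With the default 41-mers the centre adenine sits at position
#' 21, so the default `GAG` at anchor 20 places G one base upstream and one
#' base downstream of the site — the core flanking motif reported around
#' 6mA sites.
#'
#' @param pattern Motif string over A/C/G/T.
#' @param anchor 1-based position of the pattern's first base.
#' @param plantProbability Probability a positive window carries the motif.
#' @param decoyProbability Probability a negative window carries the motif
#'   at the same anchor.
#' @return A validated `MotifSpec` list.
#' @export
motifSpec <- function(pattern = "GAG", anchor = 20L,
                      plantProbability = 1, decoyProbability = 0) {
  pattern <- toupper(as.character(pattern))
  if (!nzchar(pattern) || grepl("[^ACGT]", pattern))
    stopf("motif pattern must be a non-empty string over A/C/G/T")
  anchor <- as.integer(anchor)
  if (anchor < 1L) stopf("motif anchor must be >= 1")
  for (p in c(plantProbability, decoyProbability))
    if (!is.numeric(p) || p < 0 || p > 1)
      stopf("planting probabilities must lie in [0, 1]")
  structure(list(pattern = pattern, anchor = anchor,
                 plantProbability = plantProbability,
                 decoyProbability = decoyProbability),
            class = "MotifSpec")
}

#' Configure the synthetic benchmark generator
#'
#' The generator emulates the benchmark layout: balanced classes of
#' fixed-length windows with A at the centre, background bases drawn
#' i.i.d. from `backgroundFrequencies`, and a position-anchored motif
#' planted into positives (and, with `decoyProbability`, negatives).
#' `scrambleAnchors = TRUE` switches negatives to carrying the same motif
#' at a uniformly random *other* valid anchor, making the class signal
#' purely positional.
#'
#' @param nPerClass Windows per class.
#' @param windowLength Odd window length (default 41).
#' @param backgroundFrequencies Length-4 vector of A/C/G/T frequencies
#'   summing to 1.
#' @param motif A [motifSpec()].
#' @param seed Integer RNG seed; fixing it makes output byte-identical.
#' @param scrambleAnchors Plant the motif at a random non-anchor position in
#'   negatives instead of using `decoyProbability` at the true anchor.
#' @return A validated `GeneratorConfig` list.
#' @export
generatorConfig <- function(nPerClass = 2000L, windowLength = 41L,
                            backgroundFrequencies = rep(0.25, 4),
                            motif = motifSpec(), seed = 1L,
                            scrambleAnchors = FALSE) {
  nPerClass <- as.integer(nPerClass)
  windowLength <- as.integer(windowLength)
  if (nPerClass < 1L) stopf("nPerClass must be positive")
  if (windowLength < 1L || windowLength %% 2L == 0L)
    stopf("windowLength must be a positive odd integer")
  bg <- as.numeric(backgroundFrequencies)
  if (length(bg) != 4L || any(bg < 0) || abs(sum(bg) - 1) > 1e-9)
    stopf("backgroundFrequencies must be 4 nonnegative values summing to 1")
  if (!inherits(motif, "MotifSpec")) stopf("motif must come from motifSpec()")
  mlen <- nchar(motif$pattern)
  if (motif$anchor + mlen - 1L > windowLength)
    stopf("motif (anchor %d, length %d) does not fit in a %d-bp window",
          motif$anchor, mlen, windowLength)
  ctr <- (windowLength + 1L) %/% 2L
  if (motif$anchor <= ctr && ctr <= motif$anchor + mlen - 1L) {
    if (substr(motif$pattern, ctr - motif$anchor + 1L, ctr - motif$anchor + 1L) != "A")
      stopf("motif overlaps the centre position %d with a base other than A", ctr)
  }
  structure(list(nPerClass = nPerClass, windowLength = windowLength,
                 backgroundFrequencies = bg, motif = motif, seed = as.integer(seed),
                 scrambleAnchors = isTRUE(scrambleAnchors)),
            class = "GeneratorConfig")
}

# anchors at which the pattern can be planted while keeping the centre A
validAnchors <- function(pattern, L) {
  ctr <- (L + 1L) %/% 2L
  mlen <- nchar(pattern)
  ok <- logical(L - mlen + 1L)
  for (a in seq_along(ok)) {
    ok[a] <- if (a <= ctr && ctr <= a + mlen - 1L)
      substr(pattern, ctr - a + 1L, ctr - a + 1L) == "A"
    else TRUE
  }
  which(ok)
}

#' Simulate a planted-motif benchmark dataset
#'
#' Draws `nPerClass` positive and `nPerClass` negative windows under a
#' [generatorConfig()]. All non-motif positions are i.i.d. background; the
#' centre base is always A in both classes (negatives are unmethylated
#' adenines). Deterministic for a fixed seed.
#'
#' @param config A [generatorConfig()].
#' @return A [MethylationWindows-class] dataset, positives first.
#' @examples
#' w <- simulateWindows(generatorConfig(nPerClass = 5, seed = 7))
#' classCounts(w)
#' @export
simulateWindows <- function(config) {
  if (!inherits(config, "GeneratorConfig"))
    stopf("config must come from generatorConfig()")
  L <- config$windowLength
  n <- config$nPerClass
  m <- config$motif
  ctr <- (L + 1L) %/% 2L
  bases <- c("A", "C", "G", "T")
  pat <- strsplit(m$pattern, "")[[1]]
  span <- m$anchor + seq_along(pat) - 1L

  drawClass <- function(n, plantProb, anchors) {
    x <- matrix(sample(bases, n * L, replace = TRUE,
                       prob = config$backgroundFrequencies), n, L)
    x[, ctr] <- "A"
    planted <- runif(n) < plantProb
    if (any(planted)) {
      if (length(anchors) == 1L) {
        x[planted, anchors + seq_along(pat) - 1L] <-
          matrix(pat, sum(planted), length(pat), byrow = TRUE)
      } else {
        a <- sample(anchors, sum(planted), replace = TRUE)
        rows <- which(planted)
        for (i in seq_along(rows))
          x[rows[i], a[i] + seq_along(pat) - 1L] <- pat
      }
    }
    x
  }

  withLocalSeed(config$seed, {
    posM <- drawClass(n, m$plantProbability, m$anchor)
    negM <- if (config$scrambleAnchors) {
      others <- setdiff(validAnchors(m$pattern, L), m$anchor)
      if (!length(others))
        stopf("no alternative anchors available for scrambled planting")
      drawClass(n, m$plantProbability, others)
    } else {
      drawClass(n, m$decoyProbability, m$anchor)
    }
  })
  seqs <- c(apply(posM, 1, paste, collapse = ""),
            apply(negM, 1, paste, collapse = ""))
  names(seqs) <- c(paste0("pos_", seq_len(n)), paste0("neg_", seq_len(n)))
  MethylationWindows(seqs, c(rep(1L, n), rep(0L, n)), "synthetic")
}

#' Write a simulated dataset as a positive/negative FASTA pair
#'
#' Simulates under `config` and writes `pos.fasta`, `neg.fasta` and a
#' `generator_config.yaml` provenance sidecar into `dir`. The FASTA pair is
#' in the layout consumed by [buildWindowSet()]; output is byte-identical
#' for a fixed seed.
#'
#' @param config A [generatorConfig()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
writeSimulatedFasta <- function(config, dir) {
  if (!inherits(config, "GeneratorConfig"))
    stopf("config must come from generatorConfig()")
  w <- simulateWindows(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  posPath <- file.path(dir, "pos.fasta")
  negPath <- file.path(dir, "neg.fasta")
  sidecar <- file.path(dir, "generator_config.yaml")
  s <- as.character(windowSequences(w))
  writeFastaWindows(s[windowLabels(w) == 1L], posPath)
  writeFastaWindows(s[windowLabels(w) == 0L], negPath)
  cfg <- config
  cfg$motif <- unclass(cfg$motif)
  yaml::write_yaml(unclass(cfg), sidecar)
  invisible(c(pos = posPath, neg = negPath, config = sidecar))
}
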