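test_that("FASTA reading handles records, folding, case and bad characters", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT"), f)
  r <- readFastaWindows(f)
  expect_equal(names(r), "s1")
  expect_equal(unname(as.character(r)), "ACGT")

  writeLines(c(">s1", "AC", "gt", ">s2", "TTTT"), f)
  r <- readFastaWindows(f)
  expect_equal(unname(as.character(r)), c("ACGT", "TTTT"))
  expect_equal(names(r), c("s1", "s2"))

  writeLines(c(">s1", "ACXT"), f)
  expect_error(readFastaWindows(f), "s1")

  expect_error(readFastaWindows(tempfile()), "does not exist")

  file.create(f2 <- tempfile())
  expect_length(readFastaWindows(f2), 0)
})

test_that("FASTA write/read round-trips ids and bases", {
  w <- randomWindows(20, seed = 4)
  f <- tempfile(fileext = ".fasta")
  writeFastaWindows(windowSequences(w), f)
  back <- readFastaWindows(f)
  expect_identical(as.character(back), as.character(windowSequences(w)))
})

test_that("buildWindowSet labels by file membership and validates windows", {
  w <- simulateWindows(generatorConfig(nPerClass = 3, seed = 9))
  d <- tempfile()
  dir.create(d)
  s <- as.character(windowSequences(w))
  writeFastaWindows(s[1:3], file.path(d, "pos.fasta"))
  writeFastaWindows(s[4:6], file.path(d, "neg.fasta"))
  ds <- buildWindowSet(file.path(d, "pos.fasta"), file.path(d, "neg.fasta"))
  expect_equal(windowLabels(ds), c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(length(ds), 6L)

  # wrong length
  writeFastaWindows(c(bad = substr(s[1], 1, 40)), file.path(d, "pos.fasta"))
  expect_error(buildWindowSet(file.path(d, "pos.fasta"), file.path(d, "neg.fasta")),
               "length")

  # centre base not A
  sBad <- s[1]
  substr(sBad, 21, 21) <- "G"
  writeFastaWindows(c(bad = sBad), file.path(d, "pos.fasta"))
  expect_error(buildWindowSet(file.path(d, "pos.fasta"), file.path(d, "neg.fasta")),
               "centre base")

  # N rejected with a count
  sN <- s[1]
  substr(sN, 5, 5) <- "N"
  writeFastaWindows(c(bad = sN), file.path(d, "pos.fasta"))
  expect_error(buildWindowSet(file.path(d, "pos.fasta"), file.path(d, "neg.fasta")),
               "1 positive window")

  # unbalanced classes warn but do not error
  writeFastaWindows(s[1:2], file.path(d, "pos.fasta"))
  expect_warning(buildWindowSet(file.path(d, "pos.fasta"), file.path(d, "neg.fasta")),
                 "unbalanced")
})

test_that("encoding uses the fixed A/C/G/T mapping and batches in order", {
  w <- MethylationWindows(c(x = "ACGATCG"), 1L)
  b <- encodeWindows(w, 4)
  expect_equal(unname(b[[1]]$indices[1, ]), c(0L, 1L, 2L, 0L, 3L, 1L, 2L))

  w2 <- randomWindows(130, seed = 2)
  batches <- encodeWindows(w2, 64)
  expect_equal(vapply(batches, function(b) nrow(b$indices), 0L), c(64L, 64L, 2L))
  expect_identical(unname(unlist(lapply(batches, decodeBatch))),
                   unname(as.character(windowSequences(w2))))
})

test_that("encode/decode round-trips random datasets", {
  for (seed in 1:5) {
    w <- randomWindows(17, L = 11, seed = seed)
    b <- encodeWindows(w, 5)
    expect_identical(unname(unlist(lapply(b, decodeBatch))),
                     unname(as.character(windowSequences(w))))
  }
})

test_that("k-fold splits partition indices, stratify labels and respect seeds", {
  w <- randomWindows(10, seed = 6)          # 5 positive, 5 negative
  folds <- kfoldSplit(w, 5, seed = 3)
  val <- lapply(folds, `[[`, "val")
  expect_setequal(unlist(val), 1:10)
  expect_equal(sum(lengths(val)), 10L)      # pairwise disjoint partition
  labs <- windowLabels(w)
  for (v in val) expect_equal(sort(labs[v]), c(0L, 1L))
  for (f in folds) expect_length(intersect(f$train, f$val), 0)

  expect_identical(kfoldSplit(w, 5, seed = 3), folds)
  expect_false(identical(kfoldSplit(w, 5, seed = 4), folds))

  # class ratio within one window of the dataset ratio at larger n
  w2 <- randomWindows(101, seed = 8)
  folds2 <- kfoldSplit(w2, 4, seed = 1)
  ratio <- mean(windowLabels(w2))
  for (f in folds2) {
    nv <- length(f$val)
    expect_lte(abs(sum(windowLabels(w2)[f$val]) - ratio * nv), 1)
  }

  expect_error(kfoldSplit(w, 11), "exceeds")
  expect_error(kfoldSplit(w, 1), "at least 2")
})

test_that("score TSV uses the id/score/predicted_label contract", {
  f <- tempfile(fileext = ".tsv")
  writeScoresTsv(c("a", "b"), c(0.9, 0.2), f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("id", "score", "predicted_label"))
  expect_equal(tab$predicted_label, c(1L, 0L))
})
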