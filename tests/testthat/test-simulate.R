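test_that("genome simulation is seeded, GC-faithful and validates lengths", {
  g1 <- makeGenome(c(4000L, 2000L), gc = 0.4, seed = 71)
  g2 <- makeGenome(c(4000L, 2000L), gc = 0.4, seed = 71)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(names(g1), c("chr01", "chr02"))
  expect_error(makeGenome(c(1000L, 0L)), "positive")

  # GC count within 3 sigma of Binomial(n, gc)
  n <- 100000L
  g <- as.character(makeGenome(n, gc = 0.5, seed = 72))[[1]]
  gcCount <- nchar(gsub("[AT]", "", g))
  expect_lt(abs(gcCount - n * 0.5), 3 * sqrt(n * 0.25))
})

test_that("planting duplicates the target site around the element, in both orientations", {
  g <- makeGenome(30000L, seed = 73)
  te <- toyTE(len = 80L, seed = 42)
  pl <- plantInsertions(g, te, n = 3L, tsdLen = 5L, reverseFrac = 0,
                        seed = 74)
  # length bookkeeping: each event adds te_len + tsd_len
  expect_equal(sum(nchar(as.character(pl$mutant))),
               30000L + 3L * (80L + 5L))
  expect_equal(pl$truth$tsd_end - pl$truth$tsd_start + 1L, rep(5L, 3))
  gs <- as.character(g)[[1]]
  expect_equal(pl$truth$tsd_seq,
               substring(gs, pl$truth$tsd_start, pl$truth$tsd_end))

  # local structure: left context + TSD + TE + TSD + right context
  ms <- as.character(pl$mutant)[[1]]
  for (r in seq_len(3)) {
    s <- pl$truth$tsd_start[r]; e <- pl$truth$tsd_end[r]
    expected <- paste0(substring(gs, s - 20L, e), te,
                       substring(gs, s, e + 20L))
    expect_true(grepl(expected, ms, fixed = TRUE))
  }

  # reverse orientation: the revcomp of the element sits between the TSDs
  plr <- plantInsertions(g, te, n = 1L, tsdLen = 5L, reverseFrac = 1,
                         seed = 75)
  expect_equal(plr$truth$orientation, "reverse")
  msr <- as.character(plr$mutant)[[1]]
  s <- plr$truth$tsd_start; e <- plr$truth$tsd_end
  expected <- paste0(substring(gs, s - 20L, e), revComp(te),
                     substring(gs, s, e + 20L))
  expect_true(grepl(expected, msr, fixed = TRUE))

  # 8 bp TSDs (the DNA-transposon convention) plant just as well
  pl8 <- plantInsertions(g, te, n = 2L, tsdLen = 8L, seed = 76)
  expect_equal(nchar(pl8$truth$tsd_seq), rep(8L, 2))
})

test_that("read simulation respects the coverage arithmetic, the seed, and the error-free contract", {
  g <- makeGenome(10000L, seed = 81)
  p1 <- tempfile(fileext = ".fastq")
  p2 <- tempfile(fileext = ".fastq")
  generateReads(g, p1, readLen = 100L, coverage = 30, paired = FALSE,
                seed = 82)
  expect_equal(nrow(readFastq(p1)), 3000L)  # round(30 * 10000 / 100)
  generateReads(g, p2, readLen = 100L, coverage = 30, paired = FALSE,
                seed = 82)
  expect_identical(readLines(p1), readLines(p2))

  # error-free reads are exact substrings of the genome or its revcomp
  generateReads(g, p1, readLen = 80L, coverage = 5, paired = TRUE, seed = 83)
  reads <- readFastq(p1)
  gs <- as.character(g)[[1]]
  grc <- revComp(gs)
  expect_true(all(vapply(reads$seq, function(s)
    grepl(s, gs, fixed = TRUE) || grepl(s, grc, fixed = TRUE), logical(1))))

  # substitution errors change about errorRate of the bases
  generateReads(g, p2, readLen = 80L, coverage = 5, paired = TRUE,
                errorRate = 0.02, seed = 83)
  withErr <- readFastq(p2)
  diffs <- sum(vapply(seq_len(nrow(reads)), function(i) {
    sum(strsplit(reads$seq[i], "")[[1]] != strsplit(withErr$seq[i], "")[[1]])
  }, numeric(1)))
  nBases <- sum(nchar(reads$seq))
  expect_gt(diffs / nBases, 0.01)
  expect_lt(diffs / nBases, 0.03)
})

test_that("truth scoring distinguishes exact recovery from spurious calls", {
  truth <- data.frame(chrom = "chr01", tsd_start = c(100L, 900L),
                      tsd_end = c(104L, 904L), orientation = c("forward", "reverse"),
                      te_name = "te", tsd_seq = c("AACCG", "TTGGA"),
                      stringsAsFactors = FALSE)
  calls <- data.frame(chrom = "chr01", tail_pos = c(100L, 904L),
                      head_pos = c(104L, 900L), tsd_len = 5L,
                      tsd_seq = c("AACCG", "TTGGA"),
                      direction = c("forward", "reverse"),
                      head_support = 1L, tail_support = 1L,
                      stringsAsFactors = FALSE)
  ev <- evaluateCalls(calls, truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_true(all(ev$matches$detected))

  spurious <- rbind(calls, within(calls[1, ], {
    tail_pos <- 5000L; head_pos <- 5004L; tsd_seq <- "CCCCC"
  }))
  ev <- evaluateCalls(spurious, truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 2 / 3)

  # a wrong direction is not a match
  flipped <- calls
  flipped$direction[1] <- "reverse"
  expect_equal(evaluateCalls(flipped, truth)$recall, 0.5)
})

test_that("truth tables round-trip through TSV", {
  g <- makeGenome(20000L, seed = 85)
  pl <- plantInsertions(g, toyTE(), n = 2L, seed = 86)
  p <- tempfile(fileext = ".tsv")
  writeTruthTsv(pl$truth, p)
  expect_equal(readTruthTsv(p), pl$truth)
})

test_that("the one-call experiment wrapper is reproducible and self-consistent", {
  s1 <- simulateInsertionExperiment(seed = 87, genomeLengths = 20000L,
                                    nInsertions = 2L, coverage = 10)
  s2 <- simulateInsertionExperiment(seed = 87, genomeLengths = 20000L,
                                    nInsertions = 2L, coverage = 10)
  expect_identical(as.character(s1$reference), as.character(s2$reference))
  expect_identical(readLines(s1$fastq), readLines(s2$fastq))
  expect_equal(s1$truth, s2$truth)
  # planted signatures never occur in the clean reference
  expect_equal(nrow(locateOccurrences(sigHead(s1$sig),
                                      buildRefIndex(s1$reference))), 0L)
})
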