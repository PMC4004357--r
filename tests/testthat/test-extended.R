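mkMapped <- function(id, side, chrom, pos, strand = "+", flank = "ACGTACGTACGTACGTACGT") {
  data.frame(read_id = id, side = side, detected_on = "read", flank = flank,
             flank_len = nchar(flank), chrom = chrom, pos = pos,
             ref_strand = strand, status = "unique", stringsAsFactors = FALSE)
}

test_that("identical junctions collapse into one supported cluster per (chrom, side, pos)", {
  mapped <- rbind(
    do.call(rbind, lapply(1:7, function(i)
      mkMapped(sprintf("r%d", i), "head", "chr01", 500L))),
    mkMapped("r8", "tail", "chr01", 500L),
    mkMapped("r9", "head", "chr01", 900L))
  cl <- clusterJunctions(mapped)
  expect_equal(nrow(cl), 3L)
  h500 <- cl[cl$side == "head" & cl$pos == 500L, ]
  expect_equal(h500$support, 7L)
  # longest flank is the representative, ties broken by read id
  mapped2 <- rbind(mkMapped("z", "head", "chr01", 10L, flank = strrep("A", 30)),
                   mkMapped("a", "head", "chr01", 10L, flank = strrep("C", 30)),
                   mkMapped("b", "head", "chr01", 10L, flank = strrep("G", 25)))
  cl2 <- clusterJunctions(mapped2)
  expect_equal(cl2$rep_read_id, "a")
  expect_equal(cl2$rep_flank, strrep("C", 30))
})

test_that("head/tail pairing is per-chromosome and strictly inside the window", {
  cl <- rbind(
    data.frame(chrom = "chr04", side = "head", pos = 30259056L,
               ref_strand = "+", support = 3L, rep_flank = "x",
               rep_read_id = "h"),
    data.frame(chrom = "chr04", side = "tail", pos = 30259052L,
               ref_strand = "+", support = 2L, rep_flank = "y",
               rep_read_id = "t"),
    data.frame(chrom = "chr05", side = "tail", pos = 30259056L,
               ref_strand = "+", support = 2L, rep_flank = "y",
               rep_read_id = "t2"))
  pr <- pairJunctions(cl, callerParams())
  expect_equal(nrow(pr), 1L)     # the chr05 tail never pairs across chroms
  expect_equal(pr$distance, 4L)
  expect_equal(pr$head_support, 3L)

  # strict window: distance 9 pairs, distance 10 does not
  mk <- function(d) rbind(
    data.frame(chrom = "c", side = "head", pos = 100L + d, ref_strand = "+",
               support = 1L, rep_flank = "x", rep_read_id = "h"),
    data.frame(chrom = "c", side = "tail", pos = 100L, ref_strand = "+",
               support = 1L, rep_flank = "y", rep_read_id = "t"))
  expect_equal(nrow(pairJunctions(mk(9L), callerParams())), 1L)
  expect_equal(nrow(pairJunctions(mk(10L), callerParams())), 0L)
})

test_that("TSD verification demands agreement of head flank, tail flank and reference", {
  g <- paste0(strrep("A", 99), "CATTG", strrep("C", 96))  # TSD CATTG at 100..104
  idx <- buildRefIndex(c(chr01 = g))
  good <- data.frame(
    chrom = "chr01", head_pos = 104L, tail_pos = 100L, distance = 4L,
    head_strand = "+", tail_strand = "+", head_support = 5L,
    tail_support = 4L,
    head_flank = paste0(strrep("A", 20), "CATTG"),
    tail_flank = paste0("CATTG", strrep("C", 20)), stringsAsFactors = FALSE)
  v <- verifyTsd(good, idx)
  expect_equal(nrow(v$calls), 1L)
  expect_equal(v$calls$tsd_seq, "CATTG")
  expect_equal(v$calls$tsd_len, 5L)
  expect_equal(v$calls$direction, "forward")
  expectValidCalls(v$calls)

  bad <- good
  bad$tail_flank <- paste0("CGTTG", strrep("C", 20))
  v <- verifyTsd(bad, idx)
  expect_equal(nrow(v$calls), 0L)
  expect_equal(v$rejected$reason, "flank-suffix-mismatch")

  shifted <- good
  shifted$head_pos <- 105L
  shifted$distance <- 5L
  shifted$head_flank <- paste0(strrep("A", 20), "CATTGC")
  shifted$tail_flank <- paste0("CATTGC", strrep("C", 19))
  v <- verifyTsd(shifted, idx)
  expect_equal(nrow(v$calls), 1L)  # reference substring at 100..105 is CATTGC

  # flanks agreeing with each other but not with the reference
  offRef <- shifted
  offRef$head_flank <- paste0(strrep("A", 20), "CATTGA")
  offRef$tail_flank <- paste0("CATTGA", strrep("C", 19))
  v <- verifyTsd(offRef, idx)
  expect_equal(v$rejected$reason, "reference-mismatch")
})

test_that("the extended caller recovers planted insertions exactly and calls nothing on the parent", {
  sim <- simulateInsertionExperiment(seed = 61, genomeLengths = 50000L,
                                     nInsertions = 4L, coverage = 30)
  calls <- runExtended(sim$fastq, sim$sig, sim$reference)
  expectValidCalls(calls)
  ev <- evaluateCalls(calls, sim$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_equal(nrow(calls), 4L)

  # parent-only reads: no element, no calls
  parentFq <- tempfile(fileext = ".fastq")
  generateReads(sim$reference, parentFq, coverage = 10, seed = 62)
  expect_equal(nrow(runExtended(parentFq, sim$sig, sim$reference)), 0L)
})

test_that("call-set subtraction partitions common and line-specific insertions", {
  sim <- simulateInsertionExperiment(seed = 63, genomeLengths = 50000L,
                                     nInsertions = 4L, coverage = 25)
  calls <- runExtended(sim$fastq, sim$sig, sim$reference)
  expect_equal(nrow(calls), 4L)

  d <- diffCalls(calls, calls)
  expect_equal(unname(d$summary), c(4L, 0L, 0L))

  parent <- calls[1:2, ]
  d <- diffCalls(calls, parent)
  expect_equal(unname(d$summary), c(2L, 2L, 0L))
  expect_equal(d$sampleSpecific$tsd_seq, calls$tsd_seq[3:4])

  a <- data.frame(chrom = "c1", tail_pos = c(10L, 50L, 90L),
                  head_pos = c(14L, 54L, 94L), tsd_len = 5L, tsd_seq = "AAAAA",
                  direction = "forward", head_support = 1L, tail_support = 1L)
  b <- data.frame(chrom = "c1", tail_pos = c(200L, 300L),
                  head_pos = c(204L, 304L), tsd_len = 5L, tsd_seq = "AAAAA",
                  direction = "forward", head_support = 1L, tail_support = 1L)
  expect_equal(unname(diffCalls(a, b)$summary), c(0L, 3L, 2L))
})

test_that("sequencing errors never create false loci; junction coverage keeps recall near one", {
  nRep <- 20L
  missed <- 0L
  for (r in seq_len(nRep)) {
    sim <- simulateInsertionExperiment(seed = 700 + r,
                                       genomeLengths = 50000L,
                                       nInsertions = 4L, coverage = 30,
                                       errorRate = 0.005)
    calls <- runExtended(sim$fastq, sim$sig, sim$reference)
    ev <- evaluateCalls(calls, sim$truth)
    expect_equal(ev$precision, 1)
    expectValidCalls(calls)
    missed <- missed + sum(!ev$matches$detected)
  }
  # each junction is covered by ~19 candidate reads, each error-free with
  # probability >= 0.995^100; the chance any junction lacks an error-free
  # witness is < 1e-3, so over 160 junctions more than 2 misses would
  # signal a defect rather than bad luck
  expect_lte(missed, 2L)
})
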