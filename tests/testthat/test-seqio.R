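test_that("FASTQ reader parses records, uppercases, and is gzip-transparent", {
  p <- tempfile(fileext = ".fastq")
  writeLines(c("@r1 extra words", "acgt", "+", "IIII"), p)
  rec <- readFastq(p)
  expect_equal(rec$id, "r1")
  expect_equal(rec$seq, "ACGT")
  expect_equal(rec$qual, "IIII")

  pgz <- tempfile(fileext = ".fastq.gz")
  writeToyFastq(c("a", "b"), c("ACGTACGT", "TTTTAAAA"), p)
  writeToyFastq(c("a", "b"), c("ACGTACGT", "TTTTAAAA"), pgz, gz = TRUE)
  expect_equal(readFastq(p), readFastq(pgz))
})

test_that("malformed FASTQ records are rejected with the offending line number", {
  p <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), p)
  expect_error(readFastq(p), "line 5.*'@'")
  writeLines(c("@r1", "ACGT", "+", "III"), p)
  expect_error(readFastq(p), "line 1.*lengths differ")
  writeLines(c("@r1", "ACGT", "IIII", "IIII"), p)
  expect_error(readFastq(p), "line 3.*'\\+'")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), p)
  expect_error(readFastq(p), "truncated")
})

test_that("fastqApply streams in bounded chunks", {
  p <- tempfile(fileext = ".fastq")
  n <- 103L
  writeToyFastq(sprintf("r%03d", 1:n), strrep("ACGT", 1:n %% 5 + 1), p)
  sizes <- integer()
  total <- fastqApply(p, function(ch) sizes <<- c(sizes, nrow(ch)),
                      chunkSize = 10L)
  expect_equal(total, n)
  expect_equal(sum(sizes), n)
  # memory is bounded by the chunk size, not the file size
  expect_true(all(sizes <= 10L))
})

test_that("a simulated FASTQ streams back with the expected count and read length", {
  g <- makeGenome(10000L, seed = 11)
  p <- tempfile(fileext = ".fastq")
  generateReads(g, p, readLen = 100L, coverage = 10, paired = TRUE, seed = 12)
  reads <- readFastq(p)
  expect_equal(nrow(reads), 1000L)  # round(10 * 10000 / 100)
  expect_true(all(nchar(reads$seq) == 100L))
})

test_that("FASTA reading concatenates wrapped lines and validates records", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", "ACGT"), p)
  seqs <- readFasta(p)
  expect_equal(as.character(seqs[["c1"]]), "ACGTACGT")

  writeLines(c(">c1 descr", "acgt", ">c2", "GGGG"), p)
  seqs <- readFasta(p)
  expect_equal(names(seqs), c("c1", "c2"))
  expect_equal(as.character(seqs[["c1"]]), "ACGT")

  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), p)
  expect_error(readFasta(p), "duplicate FASTA id: c1")
  writeLines(character(0), p)
  expect_error(readFasta(p), "empty")
})

test_that("FASTA writing round-trips a simulated genome", {
  g <- makeGenome(c(3000L, 2000L), seed = 3)
  p <- tempfile(fileext = ".fa")
  writeFasta(g, p)
  back <- readFasta(p)
  expect_equal(names(back), names(g))
  expect_equal(as.character(back), as.character(g))
})

test_that("group FASTA is sorted by TSD with head/tail record pairs and re-readable", {
  flanks <- data.frame(
    read_id = c("h1", "t1", "h2", "t2"),
    side = c("head", "tail", "head", "tail"),
    detected_on = "read",
    flank = c("TTAGTTTC", "GTTTCAA", "CCAACTTT", "ACTTTGGAT"),
    flank_len = c(8L, 7L, 8L, 9L), stringsAsFactors = FALSE)
  groups <- lapply(groupByTsd(flanks, 5L), selectRepresentatives)
  p <- tempfile(fileext = ".fa")
  writeGroupFasta(groups, p)
  lines <- readLines(p)
  ids <- sub("\\s.*", "", sub("^>", "", lines[startsWith(lines, ">")]))
  expect_equal(ids, c("ACTTT_head", "ACTTT_tail", "GTTTC_head", "GTTTC_tail"))

  back <- readFasta(p)
  expect_equal(length(back), 4L)
  expect_equal(as.character(back[["GTTTC_head"]]), "TTAGTTTC")

  # empty group list: empty file, no error
  p2 <- tempfile(fileext = ".fa")
  expect_silent(writeGroupFasta(list(), p2))
  expect_equal(file.size(p2), 0)
})

test_that("call TSV writes 1-based sorted rows and round-trips the fixture", {
  calls <- data.frame(chrom = "chr04", tail_pos = 30259052L,
                      head_pos = 30259056L, tsd_len = 5L, tsd_seq = "GTTTC",
                      direction = "forward", head_support = 3L,
                      tail_support = 2L, stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  writeCallsTsv(calls, p)
  lines <- readLines(p)
  expect_equal(lines[1], paste(c("chrom", "tail_junction", "head_junction",
                                 "tsd_size", "tsd_seq", "direction",
                                 "head_support", "tail_support"),
                               collapse = "\t"))
  expect_equal(lines[2], "chr04\t30259052\t30259056\t5\tGTTTC\tforward\t3\t2")

  # empty call set: header-only file
  writeCallsTsv(calls[0, ], p)
  expect_equal(length(readLines(p)), 1L)

  # all validated rice loci round-trip through the writer/reader pair
  pairs <- fixturePairs()
  fx <- data.frame(chrom = pairs$chrom, tail_pos = pairs$tail_pos,
                   head_pos = pairs$head_pos, tsd_len = pairs$tsd_size,
                   tsd_seq = pairs$tsd_head,
                   direction = tolower(pairs$direction),
                   head_support = 1L, tail_support = 1L,
                   stringsAsFactors = FALSE)
  fx <- fx[order(fx$chrom, pmin(fx$tail_pos, fx$head_pos)), ]
  rownames(fx) <- NULL
  writeCallsTsv(fx, p)
  expect_equal(readCallsTsv(p), fx)
})
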