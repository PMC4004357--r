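# shared in-code fixtures and independent oracles

# a toy TE (total length `len`) whose 8-bp termini are easy to eyeball
toyTE <- function(len = 60L, seed = 42L) {
  set.seed(seed)
  mid <- paste(sample(c("A", "C", "G", "T"), len - 16L, replace = TRUE),
               collapse = "")
  paste0("CCGGAAAT", mid, "ATTTTCGA")
}

# write a FASTQ file from id/seq vectors (qual all 'I')
writeToyFastq <- function(ids, seqs, path, gz = FALSE) {
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), con)
  path
}

# independent naive full-scan matcher: base-R string enumeration, no
# Biostrings, same uniqueness/junction contract as mapFlank
naiveRevComp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

naiveLocate <- function(seq, chroms) {
  out <- list()
  rc <- naiveRevComp(seq)
  len <- nchar(seq)
  for (nm in names(chroms)) {
    n <- nchar(chroms[[nm]])
    if (n < len) next
    windows <- substring(chroms[[nm]], 1:(n - len + 1L), len:n)
    for (std in c("+", "-")) {
      pat <- if (std == "+") seq else rc
      if (std == "-" && rc == seq) next
      pos <- which(windows == pat)
      if (length(pos)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = nm, start = pos, end = pos + len - 1L, strand = std,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

naiveMapFlank <- function(flank, side, chroms) {
  hits <- naiveLocate(flank, chroms)
  if (nrow(hits) == 0L) return(list(status = "unmapped", pos = NA))
  if (nrow(hits) > 1L) return(list(status = "multi-mapped", pos = NA))
  pos <- if (hits$strand == "+") {
    if (side == "head") hits$end else hits$start
  } else {
    if (side == "head") hits$start else hits$end
  }
  list(status = "unique", pos = pos, chrom = hits$chrom,
       strand = hits$strand)
}

# machine-check of the insertion-call invariants on any call table
expectValidCalls <- function(calls) {
  if (nrow(calls) == 0L) return(invisible(TRUE))
  expect_equal(calls$tsd_len, abs(calls$head_pos - calls$tail_pos) + 1L)
  expect_equal(nchar(calls$tsd_seq), calls$tsd_len)
  expect_equal(calls$direction,
               tsdFromJunctions(calls$tail_pos, calls$head_pos)$direction)
  expect_true(all(calls$head_support >= 1L))
  expect_true(all(calls$tail_support >= 1L))
  invisible(TRUE)
}
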