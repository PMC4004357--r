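# streaming FASTQ, FASTA and tabular call IO
#
# FASTA goes through Biostrings. FASTQ is parsed by a chunked streaming
# reader of our own: the scanner only ever needs one bounded chunk of reads
# in memory, whatever the file size, and parse errors must name the
# offending line.

.openText <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # gzfile() transparently reads both gzip and plain text
  gzfile(path, open = "rt")
}

#' Apply a function over a FASTQ file in bounded chunks
#'
#' Streams a (optionally gzipped) 4-line-record FASTQ file, calling
#' `fun(chunk)` for each chunk of at most `chunkSize` records, where
#' `chunk` is a data.frame with columns `id`, `seq` (uppercased) and
#' `qual`. Memory use is bounded by the chunk size, not the file size.
#'
#' @param path FASTQ path, plain or gzip.
#' @param fun function of one argument (the chunk data.frame); its return
#'   value is discarded.
#' @param chunkSize records per chunk.
#' @return (invisibly) the total number of records streamed.
#' @export
fastqApply <- function(path, fun, chunkSize = 10000L) {
  con <- .openText(path)
  on.exit(close(con), add = TRUE)
  total <- 0L
  lineNo <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunkSize)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ record starting at line ",
           lineNo + 4L * (length(lines) %/% 4L) + 1L, call. = FALSE)
    idx <- seq(1L, length(lines), by = 4L)
    hdr <- lines[idx]
    seq <- toupper(lines[idx + 1L])
    plus <- lines[idx + 2L]
    qual <- lines[idx + 3L]
    badHdr <- which(!startsWith(hdr, "@"))
    if (length(badHdr))
      stop("FASTQ record at line ", lineNo + 4L * (badHdr[1L] - 1L) + 1L,
           " does not start with '@'", call. = FALSE)
    badPlus <- which(!startsWith(plus, "+"))
    if (length(badPlus))
      stop("FASTQ separator line ", lineNo + 4L * (badPlus[1L] - 1L) + 3L,
           " does not start with '+'", call. = FALSE)
    badLen <- which(nchar(seq) != nchar(qual) | nchar(seq) == 0L)
    if (length(badLen))
      stop("FASTQ record at line ", lineNo + 4L * (badLen[1L] - 1L) + 1L,
           ": sequence and quality lengths differ (or empty sequence)",
           call. = FALSE)
    id <- sub("\\s.*$", "", substring(hdr, 2L))
    fun(data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE))
    total <- total + length(idx)
    lineNo <- lineNo + length(lines)
  }
  invisible(total)
}

#' Read a whole FASTQ file
#'
#' Convenience wrapper over [fastqApply()] that accumulates all records.
#' For large files prefer the streaming interface.
#'
#' @inheritParams fastqApply
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
readFastq <- function(path, chunkSize = 100000L) {
  chunks <- list()
  fastqApply(path, function(ch) chunks[[length(chunks) + 1L]] <<- ch,
             chunkSize = chunkSize)
  if (length(chunks) == 0L)
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, chunks)
}

#' Read a (multi-)FASTA file
#'
#' Wrapped lines are concatenated and sequences uppercased; record names
#' are the first whitespace-delimited token of each header.
#'
#' @param path FASTA path (gzip accepted).
#' @return named `DNAStringSet`.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop("duplicate FASTA id: ", nm[duplicated(nm)][1L], call. = FALSE)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- nm
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @return (invisibly) `path`.
#' @export
writeFasta <- function(seqs, path) {
  seqs <- .asDNAStringSet(seqs, "seqs")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Write TSD groups as multi-FASTA
#'
#' Writes the representative head and tail flank of each group, two records
#' per group with headers `{TSD}_head` / `{TSD}_tail`, groups sorted
#' lexicographically by TSD string. The free-text description carries the
#' flank length and support count, so the file is self-describing and ready
#' for an external aligner.
#'
#' @param groups list of [TSDGroup-class] objects with representatives
#'   selected (see [selectRepresentatives()]).
#' @param path output path.
#' @return (invisibly) `path`.
#' @export
writeGroupFasta <- function(groups, path) {
  if (length(groups) == 0L) {
    writeLines(character(0L), path)
    return(invisible(path))
  }
  tsds <- vapply(groups, groupTsd, character(1L))
  groups <- groups[order(tsds)]
  lines <- unlist(lapply(groups, function(g) {
    if (is.na(g@repHead) || is.na(g@repTail))
      stop("group '", g@tsd, "' is missing a representative on one side; ",
           "run selectRepresentatives() first", call. = FALSE)
    sup <- groupSupport(g)
    c(sprintf(">%s_head flank_len=%d support=%d", g@tsd, nchar(g@repHead),
              sup[["head"]]),
      g@repHead,
      sprintf(">%s_tail flank_len=%d support=%d", g@tsd, nchar(g@repTail),
              sup[["tail"]]),
      g@repTail)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

.callsTsvNames <- c("chrom", "tail_junction", "head_junction", "tsd_size",
                    "tsd_seq", "direction", "head_support", "tail_support")

#' Write insertion calls as TSV
#'
#' Tab-separated with header columns `chrom`, `tail_junction`,
#' `head_junction`, `tsd_size`, `tsd_seq`, `direction`, `head_support`,
#' `tail_support`; 1-based inclusive coordinates; rows sorted by
#' (chromosome, leftmost junction).
#'
#' @param calls insertion-call data.frame as returned by [runExtended()].
#' @param path output path.
#' @return (invisibly) `path`.
#' @export
writeCallsTsv <- function(calls, path) {
  out <- data.frame(chrom = calls$chrom,
                    tail_junction = calls$tail_pos,
                    head_junction = calls$head_pos,
                    tsd_size = calls$tsd_len,
                    tsd_seq = calls$tsd_seq,
                    direction = calls$direction,
                    head_support = calls$head_support,
                    tail_support = calls$tail_support,
                    stringsAsFactors = FALSE)
  if (nrow(out))
    out <- out[order(out$chrom, pmin(out$tail_junction, out$head_junction)), ,
               drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an insertion-call TSV
#'
#' Inverse of [writeCallsTsv()].
#'
#' @param path TSV path.
#' @return insertion-call data.frame (columns `chrom`, `tail_pos`,
#'   `head_pos`, `tsd_len`, `tsd_seq`, `direction`, `head_support`,
#'   `tail_support`).
#' @export
readCallsTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character", tsd_seq = "character",
                                  direction = "character"))
  if (!identical(names(df), .callsTsvNames))
    stop("unexpected call-table columns in ", path, call. = FALSE)
  data.frame(chrom = df$chrom, tail_pos = as.integer(df$tail_junction),
             head_pos = as.integer(df$head_junction),
             tsd_len = as.integer(df$tsd_size), tsd_seq = df$tsd_seq,
             direction = df$direction,
             head_support = as.integer(df$head_support),
             tail_support = as.integer(df$tail_support),
             stringsAsFactors = FALSE)
}
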