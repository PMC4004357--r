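# step (1) of both callers: find reads carrying a TE terminal signature and
# extract the oriented genomic flank at the junction

# vectorised scan of one batch of reads; both the reads and their reverse
# complements are searched with forward-strand rules, so flanks from the
# revcomp pass come out already oriented like plus-pass flanks
.scanChunk <- function(ids, seqs, sig) {
  dss <- Biostrings::DNAStringSet(seqs)
  passes <- list(read = dss, revcomp = Biostrings::reverseComplement(dss))
  out <- vector("list", 4L)
  j <- 0L
  for (passName in names(passes)) {
    x <- passes[[passName]]
    xs <- as.character(x)
    xl <- nchar(xs)

    # head signature: flank is everything before the match
    m <- Biostrings::vmatchPattern(sig@head, x, fixed = TRUE)
    n <- S4Vectors::elementNROWS(m)
    if (sum(n) > 0L) {
      ridx <- rep.int(seq_along(xs), n)
      st <- unlist(Biostrings::startIndex(m), use.names = FALSE)
      keep <- st > 1L
      if (any(keep)) {
        ridx2 <- ridx[keep]
        fl <- substring(xs[ridx2], 1L, st[keep] - 1L)
        j <- j + 1L
        out[[j]] <- data.frame(read_id = ids[ridx2], side = "head",
                               detected_on = passName, flank = fl,
                               flank_len = nchar(fl), stringsAsFactors = FALSE)
      }
    }

    # tail signature: flank is everything after the match
    m <- Biostrings::vmatchPattern(sig@tail, x, fixed = TRUE)
    n <- S4Vectors::elementNROWS(m)
    if (sum(n) > 0L) {
      ridx <- rep.int(seq_along(xs), n)
      en <- unlist(Biostrings::endIndex(m), use.names = FALSE)
      keep <- en < xl[ridx]
      if (any(keep)) {
        ridx2 <- ridx[keep]
        fl <- substring(xs[ridx2], en[keep] + 1L, xl[ridx2])
        j <- j + 1L
        out[[j]] <- data.frame(read_id = ids[ridx2], side = "tail",
                               detected_on = passName, flank = fl,
                               flank_len = nchar(fl), stringsAsFactors = FALSE)
      }
    }
  }
  if (j == 0L) return(.emptyFlanks())
  do.call(rbind, out[seq_len(j)])
}

#' Scan one read for TE terminal signatures
#'
#' Searches both the read and its reverse complement for exact occurrences
#' of the head and tail signatures. A head occurrence yields a head flank
#' (the bases preceding the TE 5' end), a tail occurrence a tail flank (the
#' bases following the TE 3' end); empty flanks are dropped and every
#' occurrence yields its own record. Reads carrying `N` inside the matched
#' window simply fail to match (signatures are exact).
#'
#' @param seq the read sequence (single DNA string over \{A,C,G,T,N\}).
#' @param sig a [TESignature-class].
#' @param id read identifier carried into the records.
#' @return data.frame of flank records (columns `read_id`, `side`,
#'   `detected_on`, `flank`, `flank_len`); zero rows when nothing matches.
#' @examples
#' sig <- TESignature("CCGGAAAA", "TTTTTCGA")
#' scanRead("ATTGCTAACCGGAAAATTTT", sig)
#' @export
scanRead <- function(seq, sig, id = "read1") {
  stopifnot(is.character(seq), length(seq) == 1L)
  .assertDna(toupper(seq), allowN = TRUE, what = "read")
  .scanChunk(id, toupper(seq), sig)
}

#' Scan a read set (or FASTQ file) for junction-bearing reads
#'
#' Streams the reads, applies [scanRead()] logic in vectorised batches, and
#' keeps flanks of at least `minFlankBasic` bp (basic mode: the flank must
#' contain the whole TSD) or `minFlankMap` bp (extended mode: long enough
#' for specific reference placement). The per-side matched-record counts
#' are attached as attribute `"side_counts"`.
#'
#' @param reads FASTQ path (plain or gzip) or a data.frame with columns
#'   `id`, `seq`.
#' @param sig a [TESignature-class].
#' @param params a [CallerParams-class]; in basic mode `tsdLen` (via
#'   `minFlankBasic`) must be set.
#' @param mode `"extended"` (default) or `"basic"` — selects the flank
#'   length threshold.
#' @param chunkSize records per streamed chunk when `reads` is a path.
#' @return data.frame of flank records, as [scanRead()].
#' @export
scanReads <- function(reads, sig, params = callerParams(),
                      mode = c("extended", "basic"), chunkSize = 20000L) {
  mode <- match.arg(mode)
  minLen <- if (mode == "basic") params@minFlankBasic else params@minFlankMap
  if (is.na(minLen))
    stop("basic mode needs tsdLen (or minFlankBasic) in callerParams()",
         call. = FALSE)
  acc <- list()
  collect <- function(ch) {
    fl <- .scanChunk(ch$id, ch$seq, sig)
    fl <- fl[fl$flank_len >= minLen, , drop = FALSE]
    if (nrow(fl)) acc[[length(acc) + 1L]] <<- fl
  }
  if (is.character(reads)) {
    fastqApply(reads, collect, chunkSize = chunkSize)
  } else {
    stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
    if (nrow(reads)) {
      starts <- seq(1L, nrow(reads), by = chunkSize)
      for (s in starts) {
        e <- min(s + chunkSize - 1L, nrow(reads))
        collect(reads[s:e, , drop = FALSE])
      }
    }
  }
  flanks <- if (length(acc)) do.call(rbind, acc) else .emptyFlanks()
  rownames(flanks) <- NULL
  attr(flanks, "side_counts") <- c(head = sum(flanks$side == "head"),
                                   tail = sum(flanks$side == "tail"))
  flanks
}
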