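# deterministic flank placement on the reference: exact, full-length,
# genome-wide unique matches only

#' Locate all exact occurrences of a sequence in the reference
#'
#' Searches the plus strand for `seq` and for its reverse complement
#' (reported as minus-strand hits in plus-strand coordinates). A
#' reverse-complement-palindromic query is counted once, on the plus
#' strand.
#'
#' @param seq DNA string.
#' @param index a [RefIndex-class].
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
locateOccurrences <- function(seq, index) {
  stopifnot(is(index, "RefIndex"), is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  hitsOn <- function(pat, strand) {
    m <- Biostrings::vmatchPattern(pat, index@seqs, fixed = TRUE)
    n <- S4Vectors::elementNROWS(m)
    if (sum(n) == 0L) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE))
    }
    st <- unlist(Biostrings::startIndex(m), use.names = FALSE)
    data.frame(chrom = rep.int(names(index@seqs), n), start = st,
               end = st + nchar(pat) - 1L, strand = strand,
               stringsAsFactors = FALSE)
  }
  rc <- revComp(seq)
  out <- hitsOn(seq, "+")
  if (rc != seq) out <- rbind(out, hitsOn(rc, "-"))
  out
}

# single-flank placement; returns a one-row data.frame
.mapOne <- function(flank, side, index) {
  hits <- locateOccurrences(flank, index)
  if (nrow(hits) == 0L) {
    return(data.frame(chrom = NA_character_, pos = NA_integer_,
                      ref_strand = NA_character_, status = "unmapped",
                      stringsAsFactors = FALSE))
  }
  if (nrow(hits) > 1L) {
    return(data.frame(chrom = NA_character_, pos = NA_integer_,
                      ref_strand = NA_character_, status = "multi-mapped",
                      stringsAsFactors = FALSE))
  }
  # junction base = flank base adjacent to the TE: last base of a head
  # flank, first base of a tail flank; mirrored for minus-strand placement,
  # always reported in plus-strand coordinates
  pos <- if (hits$strand == "+") {
    if (side == "head") hits$end else hits$start
  } else {
    if (side == "head") hits$start else hits$end
  }
  data.frame(chrom = hits$chrom, pos = pos, ref_strand = hits$strand,
             status = "unique", stringsAsFactors = FALSE)
}

#' Place one junction flank on the reference
#'
#' The flank must match the reference exactly, at full length, at exactly
#' one location genome-wide (either strand); otherwise no junction is
#' reported and the status says why (`"unmapped"` or `"multi-mapped"`).
#' This strict contract trades a little sensitivity in repetitive context
#' for deterministic, version-independent placement — insertions inside
#' sequence that recurs identically elsewhere are out of reach by design.
#'
#' @param flank flank sequence (DNA string).
#' @param side `"head"` or `"tail"` — which element terminus the flank
#'   borders; determines which flank end is the junction base.
#' @param index a [RefIndex-class].
#' @return one-row data.frame with columns `chrom`, `pos` (1-based
#'   plus-strand junction coordinate), `ref_strand`, `status`.
#' @export
mapFlank <- function(flank, side = c("head", "tail"), index) {
  side <- match.arg(side)
  .mapOne(toupper(flank), side, index)
}

#' Place a set of flank records on the reference
#'
#' Vectorised [mapFlank()] over a flank-record data.frame; identical
#' (side, flank) strings are located once and the result reused.
#'
#' @param flanks flank-record data.frame from [scanReads()].
#' @param index a [RefIndex-class].
#' @param minLen flanks shorter than this are not submitted (status
#'   `"too-short"`).
#' @return `flanks` with columns `chrom`, `pos`, `ref_strand`, `status`
#'   appended.
#' @export
mapFlanks <- function(flanks, index, minLen = 20L) {
  n <- nrow(flanks)
  res <- data.frame(chrom = rep(NA_character_, n), pos = rep(NA_integer_, n),
                    ref_strand = rep(NA_character_, n),
                    status = rep("too-short", n), stringsAsFactors = FALSE)
  eligible <- which(flanks$flank_len >= minLen)
  if (length(eligible)) {
    key <- paste0(flanks$side[eligible], ":", flanks$flank[eligible])
    uk <- !duplicated(key)
    uniqMap <- do.call(rbind, Map(.mapOne, flanks$flank[eligible][uk],
                                  flanks$side[eligible][uk],
                                  MoreArgs = list(index = index)))
    rownames(uniqMap) <- key[uk]
    res[eligible, ] <- uniqMap[key, , drop = FALSE]
  }
  out <- cbind(flanks, res)
  rownames(out) <- NULL
  out
}
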