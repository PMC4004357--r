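# domain primitives: reverse complement, signature derivation, TSD arithmetic

#' Reverse complement
#'
#' Vectorised reverse complement over the alphabet \{A,C,G,T,N\}; `N` maps
#' to `N`. Any other character is an error.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of the same length.
#' @examples
#' revComp("CATGATGAAATAACATA")  # the P-element head; yields its TIR partner
#' @export
revComp <- function(seq) {
  if (!is.character(seq)) stop("seq must be character", call. = FALSE)
  seq <- toupper(seq)
  .assertDna(seq, allowN = TRUE, what = "seq")
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

#' @rdname canonicalTsd
#' @title Orientation-free canonical form of a TSD string
#' @description Returns the lexicographic minimum of a TSD string and its
#'   reverse complement. The reference-free caller reports TSDs in read
#'   orientation, the reference-based caller on the plus strand; the
#'   canonical form is the representation under which the two agree.
#' @param tsd character vector of TSD strings.
#' @return character vector.
#' @export canonicalTsd
NULL

#' Derive a TE signature from the element sequence
#'
#' Takes the first and last `k` bases of the element as head and tail
#' signatures. For a TIR DNA transposon the tail equals the reverse
#' complement of the head.
#'
#' @param te the element sequence: a single DNA string, a `DNAString`, or a
#'   (length-1) `DNAStringSet` / FASTA path.
#' @param k signature length in bp (default 17).
#' @param name element name; defaults to the sequence name when available.
#' @return A [TESignature-class].
#' @export
signatureFromTE <- function(te, k = 17L, name = NULL) {
  seqs <- .asDNAStringSet(te, "te")
  if (length(seqs) != 1L)
    stop("te must contain exactly one sequence", call. = FALSE)
  if (is.null(name)) {
    name <- if (!is.null(names(seqs)) && nzchar(names(seqs)[1L]))
      names(seqs)[1L] else "TE"
  }
  s <- as.character(seqs[[1L]])
  k <- as.integer(k)
  n <- nchar(s)
  if (n < 2L * k)
    stop("TE sequence (", n, " bp) is shorter than 2k = ", 2L * k, " bp",
         call. = FALSE)
  head <- substring(s, 1L, k)
  tail <- substring(s, n - k + 1L, n)
  if (grepl("N", head, fixed = TRUE) || grepl("N", tail, fixed = TRUE))
    stop("TE terminal window contains N; supply explicit signatures with ",
         "TESignature()", call. = FALSE)
  TESignature(head, tail, name = name)
}

#' Probability that two independent TSDs coincide
#'
#' The chance that two independent uniform L-mers are identical, `4^-L`.
#' For a 5 bp TSD this is 1/1024: the reference-free caller merges two
#' insertions into one group with this probability per pair, which stays
#' negligible at the ~10 transpositions per line typical of activated LTR
#' retrotransposons, but grows relevant for short TSDs or very active
#' elements — the motivation for the reference-based caller.
#'
#' @param L TSD length in bp (>= 0).
#' @return numeric probability.
#' @examples
#' tsdCollisionProb(5)  # 1/1024
#' @export
tsdCollisionProb <- function(L) {
  if (!is.numeric(L) || any(!is.finite(L)) || any(L < 0) || any(L != round(L)))
    stop("L must be a nonnegative integer", call. = FALSE)
  4^(-L)
}

#' TSD length and element orientation from junction coordinates
#'
#' Both junction coordinates lie on the pre-insertion reference; the tail
#' and head junctions bracket the duplicated site, so its length is
#' `|head - tail| + 1`. The element orientation follows from coordinate
#' order: head junction downstream of the tail junction means the element
#' inserted in forward orientation, upstream means reverse. Equal
#' coordinates (a 1 bp TSD) are reported forward by convention.
#'
#' @param tailPos,headPos 1-based junction coordinates on one chromosome
#'   (vectorised).
#' @return data.frame with columns `tsd_len` and `direction`.
#' @examples
#' tsdFromJunctions(30259052, 30259056)  # 5 bp, forward
#' @export
tsdFromJunctions <- function(tailPos, headPos) {
  stopifnot(is.numeric(tailPos), is.numeric(headPos),
            length(tailPos) == length(headPos))
  data.frame(
    tsd_len = as.integer(abs(headPos - tailPos) + 1),
    direction = ifelse(headPos >= tailPos, "forward", "reverse"),
    stringsAsFactors = FALSE)
}
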