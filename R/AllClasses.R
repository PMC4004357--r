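#' TE terminal signature
#'
#' Holds the k-bp 5' (head) and 3' (tail) terminal sequences of the target
#' transposable element. These two k-mers are what the scanner looks for in
#' reads; k = 17 is the default used throughout, a length at which terminal
#' k-mers of typical elements are effectively unique in host genomes while
#' still leaving most of a 100 bp read for the genomic flank.
#'
#' @slot name element name.
#' @slot head first k bases of the element (5' terminus).
#' @slot tail last k bases of the element (3' terminus).
#' @slot k signature length in bp (>= 8; no ambiguity codes allowed).
#'
#' @seealso [signatureFromTE()] to derive a signature from a TE sequence,
#'   [TESignature()] to build one from explicit k-mers.
#' @exportClass TESignature
setClass("TESignature",
         representation(name = "character", head = "character",
                        tail = "character", k = "integer"))

setValidity("TESignature", function(object) {
  msg <- character()
  if (length(object@head) != 1L || length(object@tail) != 1L)
    msg <- c(msg, "head and tail must be single strings")
  if (object@k < 8L)
    msg <- c(msg, "signature length k must be >= 8")
  if (nchar(object@head) != object@k || nchar(object@tail) != object@k)
    msg <- c(msg, "head and tail must both have length k")
  if (grepl("[^ACGT]", object@head) || grepl("[^ACGT]", object@tail))
    msg <- c(msg, "signatures must be over {A,C,G,T} (no N)")
  if (length(msg)) msg else TRUE
})

#' Construct a TE signature from explicit terminal k-mers
#'
#' @param head first k bases of the element (5' end).
#' @param tail last k bases of the element (3' end); same length as `head`.
#' @param name element name (metadata only).
#' @return A [TESignature-class] object.
#' @examples
#' # P-element terminal inverted repeat: tail is the revcomp of the head
#' sig <- TESignature("CATGATGAAATAACATA", "TATGTTATTTCATCATG", name = "P-element")
#' @export
TESignature <- function(head, tail, name = "TE") {
  head <- toupper(head); tail <- toupper(tail)
  if (nchar(head) != nchar(tail))
    stop("head and tail signatures must have equal length", call. = FALSE)
  new("TESignature", name = name, head = head, tail = tail,
      k = nchar(head))
}

setMethod("show", "TESignature", function(object) {
  cat("TESignature '", object@name, "' (k = ", object@k, ")\n",
      "  head: 5'-", object@head, "\n",
      "  tail:    ", object@tail, "-3'\n", sep = "")
})

#' @describeIn TESignature-class signature length k (bp).
#' @param x,object a `TESignature`.
#' @export
sigLength <- function(x) x@k

#' @describeIn TESignature-class head (5'-terminal) k-mer.
#' @export
sigHead <- function(x) x@head

#' @describeIn TESignature-class tail (3'-terminal) k-mer.
#' @export
sigTail <- function(x) x@tail


#' Caller parameters
#'
#' Tuning knobs shared by the basic and extended callers.
#'
#' @slot tsdLen expected TSD length L in bp (basic caller only; the extended
#'   caller infers it from junction spacing and may leave it `NA`). TSDs of
#'   LTR retrotransposons and TIR DNA transposons are under 10 bp, so
#'   1 <= L <= 10.
#' @slot pairWindow maximum head/tail junction distance in bp for extended
#'   pairing; strict (distance must be `< pairWindow`). Default 10.
#' @slot minFlankBasic minimum flank length kept in basic mode (defaults to
#'   L: the flank must at least contain the whole TSD).
#' @slot minFlankMap minimum flank length submitted to reference mapping in
#'   extended mode (default 20 bp, for placement specificity).
#'
#' @exportClass CallerParams
setClass("CallerParams",
         representation(tsdLen = "integer", pairWindow = "integer",
                        minFlankBasic = "integer", minFlankMap = "integer"))

setValidity("CallerParams", function(object) {
  msg <- character()
  if (!is.na(object@tsdLen)) {
    if (object@tsdLen < 1L || object@tsdLen > 10L)
      msg <- c(msg, "tsdLen must satisfy 1 <= tsdLen <= 10")
    if (object@pairWindow < object@tsdLen)
      msg <- c(msg, "pairWindow must be >= tsdLen")
  }
  if (object@pairWindow < 1L) msg <- c(msg, "pairWindow must be >= 1")
  if (!is.na(object@minFlankBasic) && object@minFlankBasic < 1L)
    msg <- c(msg, "minFlankBasic must be >= 1")
  if (object@minFlankMap < 1L) msg <- c(msg, "minFlankMap must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Build caller parameters
#'
#' @param tsdLen expected TSD length in bp (needed by the basic caller only).
#' @param pairWindow strict upper bound on head/tail junction distance (bp).
#' @param minFlankBasic minimum flank length kept in basic mode; defaults to
#'   `tsdLen`.
#' @param minFlankMap minimum flank length mapped in extended mode.
#' @return A [CallerParams-class] object.
#' @export
callerParams <- function(tsdLen = NA, pairWindow = 10L,
                         minFlankBasic = NULL, minFlankMap = 20L) {
  tsdLen <- as.integer(tsdLen)
  if (is.null(minFlankBasic)) minFlankBasic <- tsdLen
  new("CallerParams", tsdLen = tsdLen, pairWindow = as.integer(pairWindow),
      minFlankBasic = as.integer(minFlankBasic),
      minFlankMap = as.integer(minFlankMap))
}

setMethod("show", "CallerParams", function(object) {
  cat("CallerParams: tsdLen =", object@tsdLen,
      "| pairWindow <", object@pairWindow,
      "| minFlankBasic =", object@minFlankBasic,
      "| minFlankMap =", object@minFlankMap, "\n")
})


#' Reference index for exact flank placement
#'
#' Wraps the reference chromosomes and answers exact substring-location
#' queries on both strands ([locateOccurrences()], [mapFlank()]). It is the
#' package's deterministic replacement for an external aligner: a flank is
#' only placed when it matches the reference exactly, at full length, at
#' exactly one genomic location.
#'
#' @slot seqs named `DNAStringSet` of uppercased chromosome sequences.
#' @seealso [buildRefIndex()]
#' @exportClass RefIndex
setClass("RefIndex", representation(seqs = "DNAStringSet"))

setValidity("RefIndex", function(object) {
  msg <- character()
  if (length(object@seqs) == 0L) msg <- c(msg, "reference has no sequences")
  nm <- names(object@seqs)
  if (is.null(nm) || any(nm == "")) msg <- c(msg, "chromosomes must be named")
  if (anyDuplicated(nm))
    msg <- c(msg, paste0("duplicate chromosome name: ", nm[duplicated(nm)][1L]))
  if (length(msg)) msg else TRUE
})

#' Build a reference index
#'
#' @param reference FASTA path, named character vector or `DNAStringSet`.
#' @return A [RefIndex-class] object.
#' @export
buildRefIndex <- function(reference) {
  seqs <- .asDNAStringSet(reference, "reference")
  if (length(seqs) == 0L) stop("reference FASTA is empty", call. = FALSE)
  new("RefIndex", seqs = seqs)
}

setMethod("show", "RefIndex", function(object) {
  cat("RefIndex:", length(object@seqs), "chromosome(s),",
      sum(Biostrings::width(object@seqs)), "bp total\n")
})

#' @describeIn RefIndex-class named vector of chromosome lengths (bp).
#' @param x a `RefIndex`.
#' @export
chromLengths <- function(x) {
  stats::setNames(Biostrings::width(x@seqs), names(x@seqs))
}


#' A TSD group (basic caller unit)
#'
#' All head flanks whose suffix, and tail flanks whose prefix, equal one TSD
#' string of length L. After [selectRepresentatives()] the longest flank on
#' each side is recorded; the representative pair is what gets written to
#' the group FASTA and, with a reference at hand, mapped to a locus.
#'
#' @slot tsd the shared TSD string (read orientation).
#' @slot headFlanks,tailFlanks data.frames of flank records (columns
#'   `read_id`, `side`, `detected_on`, `flank`, `flank_len`).
#' @slot repHead,repTail representative (longest) flank sequence per side,
#'   `NA` until selected.
#' @slot repHeadId,repTailId read ids of the representatives.
#' @exportClass TSDGroup
setClass("TSDGroup",
         representation(tsd = "character",
                        headFlanks = "data.frame", tailFlanks = "data.frame",
                        repHead = "character", repTail = "character",
                        repHeadId = "character", repTailId = "character"))

setValidity("TSDGroup", function(object) {
  msg <- character()
  L <- nchar(object@tsd)
  hf <- object@headFlanks$flank
  tf <- object@tailFlanks$flank
  if (length(hf) == 0L || length(tf) == 0L)
    msg <- c(msg, "both head and tail flank sets must be nonempty")
  if (length(hf) && !all(substring(hf, nchar(hf) - L + 1L) == object@tsd))
    msg <- c(msg, "every head flank must end with the group TSD")
  if (length(tf) && !all(substring(tf, 1L, L) == object@tsd))
    msg <- c(msg, "every tail flank must start with the group TSD")
  if (!is.na(object@repHead) &&
      nchar(object@repHead) < max(c(0L, nchar(hf))))
    msg <- c(msg, "repHead must have maximal length on the head side")
  if (!is.na(object@repTail) &&
      nchar(object@repTail) < max(c(0L, nchar(tf))))
    msg <- c(msg, "repTail must have maximal length on the tail side")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TSDGroup", function(object) {
  cat("TSDGroup '", object@tsd, "': ",
      nrow(object@headFlanks), " head / ",
      nrow(object@tailFlanks), " tail flank(s)", sep = "")
  if (!is.na(object@repHead)) {
    cat("; representatives ", nchar(object@repHead), "/",
        nchar(object@repTail), " bp", sep = "")
  }
  cat("\n")
})

#' @describeIn TSDGroup-class the group's TSD string.
#' @param x a `TSDGroup`.
#' @export
groupTsd <- function(x) x@tsd

#' @describeIn TSDGroup-class head/tail support (number of flanks per side),
#'   as a named integer vector.
#' @export
groupSupport <- function(x) {
  c(head = nrow(x@headFlanks), tail = nrow(x@tailFlanks))
}
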