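# reference-free caller: group flanks by shared TSD string, keep the longest
# representative pair per group

#' Group junction flanks by their TSD string
#'
#' Head flanks are keyed by their length-`L` suffix, tail flanks by their
#' length-`L` prefix. A key seen on both sides becomes a group — the two
#' flank sets then witness the two junctions of one insertion sharing that
#' duplicated site. Keys with evidence on only one side are dropped: a
#' lone-sided key cannot be distinguished from a truncated element or a
#' chance signature hit.
#'
#' @param flanks flank-record data.frame from [scanReads()]; all records
#'   must have `flank_len >= L`.
#' @param L TSD length in bp.
#' @return list of [TSDGroup-class] objects, sorted by TSD string.
#' @export
groupByTsd <- function(flanks, L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be >= 1", call. = FALSE)
  if (nrow(flanks) && any(flanks$flank_len < L))
    stop("all flanks must have flank_len >= L", call. = FALSE)
  heads <- flanks[flanks$side == "head", , drop = FALSE]
  tails <- flanks[flanks$side == "tail", , drop = FALSE]
  headKey <- substring(heads$flank, heads$flank_len - L + 1L)
  tailKey <- substring(tails$flank, 1L, L)
  common <- sort(intersect(headKey, tailKey))
  lapply(common, function(tsd) {
    new("TSDGroup", tsd = tsd,
        headFlanks = heads[headKey == tsd, , drop = FALSE],
        tailFlanks = tails[tailKey == tsd, , drop = FALSE],
        repHead = NA_character_, repTail = NA_character_,
        repHeadId = NA_character_, repTailId = NA_character_)
  })
}

#' Select the longest representative flank pair of a group
#'
#' Picks the maximal-length flank on each side; ties go to the
#' lexicographically smallest read id, so the choice is canonical and
#' independent of read order.
#'
#' @param group a [TSDGroup-class] with both sides nonempty.
#' @return the group with `repHead`/`repTail` (and their read ids) set.
#' @export
selectRepresentatives <- function(group) {
  pick <- function(df, side) {
    if (nrow(df) == 0L)
      stop("group '", group@tsd, "' has no ", side, " flanks", call. = FALSE)
    df <- df[order(-df$flank_len, df$read_id), , drop = FALSE]
    df[1L, , drop = FALSE]
  }
  h <- pick(group@headFlanks, "head")
  t <- pick(group@tailFlanks, "tail")
  group@repHead <- h$flank
  group@repHeadId <- h$read_id
  group@repTail <- t$flank
  group@repTailId <- t$read_id
  validObject(group)
  group
}

#' Run the reference-free (basic) caller
#'
#' Scans the reads for signature-bearing junctions, groups flanks by their
#' length-`tsdLen` TSD string, selects the longest representative pair per
#' group, and (optionally) writes the representative flanks as a sorted
#' multi-FASTA. No reference genome is used, so insertions are identified
#' by TSD string, not by locus — two insertions that happen to duplicate
#' the same string merge into one group (probability
#' [tsdCollisionProb()]`(L)` per pair).
#'
#' @param reads FASTQ path or data.frame (see [scanReads()]).
#' @param sig a [TESignature-class].
#' @param params a [CallerParams-class] with `tsdLen` set, or a single
#'   number taken as the TSD length.
#' @param out optional path; when given, the group FASTA is written there.
#' @return list of [TSDGroup-class] objects with representatives selected,
#'   sorted by TSD string.
#' @export
runBasic <- function(reads, sig, params, out = NULL) {
  if (is.numeric(params)) params <- callerParams(tsdLen = params)
  if (is.na(params@tsdLen))
    stop("the basic caller requires tsdLen", call. = FALSE)
  flanks <- scanReads(reads, sig, params, mode = "basic")
  groups <- groupByTsd(flanks, params@tsdLen)
  groups <- lapply(groups, selectRepresentatives)
  if (!is.null(out)) writeGroupFasta(groups, out)
  groups
}

#' Tabulate a list of TSD groups
#'
#' @param groups list of [TSDGroup-class] objects (representatives
#'   selected).
#' @return data.frame with one row per group: `tsd`, `rep_head`,
#'   `rep_tail`, `head_support`, `tail_support`.
#' @export
groupsTable <- function(groups) {
  if (length(groups) == 0L) {
    return(data.frame(tsd = character(), rep_head = character(),
                      rep_tail = character(), head_support = integer(),
                      tail_support = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(groups, function(g) {
    sup <- groupSupport(g)
    data.frame(tsd = g@tsd, rep_head = g@repHead, rep_tail = g@repTail,
               head_support = sup[["head"]], tail_support = sup[["tail"]],
               stringsAsFactors = FALSE)
  }))
}
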