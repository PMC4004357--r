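# reference-based caller: cluster mapped junctions, pair head/tail within
# the window, verify the TSD against flanks and reference

#' Collapse mapped flanks into junction clusters
#'
#' Reads witnessing the same junction map to the same (chromosome, side,
#' position); each such triple becomes one cluster whose support is the
#' read count. The cluster keeps its longest flank (ties to the smallest
#' read id) as representative for TSD verification, mirroring the
#' longest-pair selection of the reference-free caller.
#'
#' @param mapped output of [mapFlanks()]; only rows with
#'   `status == "unique"` are used.
#' @return data.frame with columns `chrom`, `side`, `pos`, `ref_strand`,
#'   `support`, `rep_flank`, `rep_read_id`.
#' @export
clusterJunctions <- function(mapped) {
  ok <- mapped[!is.na(mapped$status) & mapped$status == "unique", ,
               drop = FALSE]
  if (nrow(ok) == 0L) return(.emptyClusters())
  key <- paste(ok$chrom, ok$side, ok$pos, sep = "\r")
  ok <- ok[order(key, -ok$flank_len, ok$read_id), , drop = FALSE]
  # after sorting, the first row of each key block is the representative
  keySorted <- paste(ok$chrom, ok$side, ok$pos, sep = "\r")
  first <- !duplicated(keySorted)
  support <- as.integer(table(keySorted)[keySorted[first]])
  data.frame(chrom = ok$chrom[first], side = ok$side[first],
             pos = ok$pos[first], ref_strand = ok$ref_strand[first],
             support = support, rep_flank = ok$flank[first],
             rep_read_id = ok$read_id[first], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Pair head and tail junction clusters within the window
#'
#' Every (head, tail) cluster pair on one chromosome whose junction
#' distance is strictly below `pairWindow` becomes a candidate insertion.
#' A cluster may take part in several candidates at this stage; TSD
#' verification ([verifyTsd()]) is what weeds out spurious combinations.
#'
#' @param clusters output of [clusterJunctions()].
#' @param params a [CallerParams-class] (`pairWindow`, default 10, strict).
#' @return data.frame of candidate pairs with columns `chrom`, `head_pos`,
#'   `tail_pos`, `distance`, `head_strand`, `tail_strand`, `head_support`,
#'   `tail_support`, `head_flank`, `tail_flank`.
#' @export
pairJunctions <- function(clusters, params = callerParams()) {
  empty <- data.frame(chrom = character(), head_pos = integer(),
                      tail_pos = integer(), distance = integer(),
                      head_strand = character(), tail_strand = character(),
                      head_support = integer(), tail_support = integer(),
                      head_flank = character(), tail_flank = character(),
                      stringsAsFactors = FALSE)
  heads <- clusters[clusters$side == "head", , drop = FALSE]
  tails <- clusters[clusters$side == "tail", , drop = FALSE]
  if (nrow(heads) == 0L || nrow(tails) == 0L) return(empty)
  out <- lapply(intersect(unique(heads$chrom), unique(tails$chrom)),
                function(ch) {
    h <- heads[heads$chrom == ch, , drop = FALSE]
    t <- tails[tails$chrom == ch, , drop = FALSE]
    g <- expand.grid(hi = seq_len(nrow(h)), ti = seq_len(nrow(t)))
    d <- abs(h$pos[g$hi] - t$pos[g$ti])
    keep <- d < params@pairWindow
    if (!any(keep)) return(NULL)
    g <- g[keep, , drop = FALSE]
    data.frame(chrom = ch, head_pos = h$pos[g$hi], tail_pos = t$pos[g$ti],
               distance = d[keep], head_strand = h$ref_strand[g$hi],
               tail_strand = t$ref_strand[g$ti],
               head_support = h$support[g$hi], tail_support = t$support[g$ti],
               head_flank = h$rep_flank[g$hi], tail_flank = t$rep_flank[g$ti],
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Verify the TSD of candidate junction pairs
#'
#' For each candidate pair the putative TSD span is
#' `[min(pos), max(pos)]` on the reference. The pair is accepted only when
#' three independent witnesses of the duplicated site agree exactly: the
#' length-`len` suffix of the representative head flank, the length-`len`
#' prefix of the representative tail flank (each reverse-complemented to
#' the plus strand when its flank was placed on the minus strand), and the
#' reference substring over the span. Accepted pairs become insertion
#' calls; rejected pairs carry a reason.
#'
#' @param pairs output of [pairJunctions()].
#' @param index a [RefIndex-class] for the same reference the flanks were
#'   mapped to.
#' @return list with `calls` (insertion-call data.frame: `chrom`,
#'   `tail_pos`, `head_pos`, `tsd_len`, `tsd_seq`, `direction`,
#'   `head_support`, `tail_support`) and `rejected` (the failed pairs plus
#'   a `reason` column).
#' @export
verifyTsd <- function(pairs, index) {
  calls <- .emptyCalls()
  rejected <- cbind(pairs[0L, , drop = FALSE],
                    data.frame(reason = character(), stringsAsFactors = FALSE))
  if (nrow(pairs) == 0L) return(list(calls = calls, rejected = rejected))
  chromStr <- as.character(index@seqs)
  resCalls <- list()
  resRej <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    lo <- min(p$head_pos, p$tail_pos)
    hi <- max(p$head_pos, p$tail_pos)
    len <- hi - lo + 1L
    reason <- NULL
    if (nchar(p$head_flank) < len || nchar(p$tail_flank) < len) {
      reason <- "flank-too-short"
    } else {
      refTsd <- substring(chromStr[[p$chrom]], lo, hi)
      headTsd <- substring(p$head_flank, nchar(p$head_flank) - len + 1L)
      if (p$head_strand == "-") headTsd <- revComp(headTsd)
      tailTsd <- substring(p$tail_flank, 1L, len)
      if (p$tail_strand == "-") tailTsd <- revComp(tailTsd)
      if (headTsd != tailTsd) {
        reason <- "flank-suffix-mismatch"
      } else if (headTsd != refTsd) {
        reason <- "reference-mismatch"
      }
    }
    if (is.null(reason)) {
      dd <- tsdFromJunctions(p$tail_pos, p$head_pos)
      resCalls[[length(resCalls) + 1L]] <- data.frame(
        chrom = p$chrom, tail_pos = p$tail_pos, head_pos = p$head_pos,
        tsd_len = dd$tsd_len, tsd_seq = substring(chromStr[[p$chrom]], lo, hi),
        direction = dd$direction, head_support = p$head_support,
        tail_support = p$tail_support, stringsAsFactors = FALSE)
    } else {
      resRej[[length(resRej) + 1L]] <- cbind(p, data.frame(
        reason = reason, stringsAsFactors = FALSE))
    }
  }
  if (length(resCalls)) calls <- do.call(rbind, resCalls)
  if (length(resRej)) rejected <- do.call(rbind, resRej)
  rownames(calls) <- rownames(rejected) <- NULL
  list(calls = calls, rejected = rejected)
}

#' Run the reference-based (extended) caller
#'
#' Full pipeline: scan reads for signature junctions, place each flank
#' uniquely on the reference, cluster identical junctions, pair head/tail
#' clusters within the window, verify TSDs, and report calls sorted by
#' locus. No TSD length is required — it is read off the junction spacing.
#'
#' @param reads FASTQ path or data.frame (see [scanReads()]).
#' @param sig a [TESignature-class].
#' @param reference FASTA path, `DNAStringSet` or [RefIndex-class].
#' @param params a [CallerParams-class].
#' @param out optional path for the call TSV ([writeCallsTsv()]).
#' @return insertion-call data.frame (see [verifyTsd()]); the rejected
#'   candidate pairs are attached as attribute `"rejected"`.
#' @export
runExtended <- function(reads, sig, reference, params = callerParams(),
                        out = NULL) {
  index <- if (is(reference, "RefIndex")) reference else buildRefIndex(reference)
  flanks <- scanReads(reads, sig, params, mode = "extended")
  mapped <- mapFlanks(flanks, index, minLen = params@minFlankMap)
  clusters <- clusterJunctions(mapped)
  pairs <- pairJunctions(clusters, params)
  ver <- verifyTsd(pairs, index)
  calls <- ver$calls
  if (nrow(calls)) {
    calls <- calls[order(calls$chrom, pmin(calls$tail_pos, calls$head_pos)), ,
                   drop = FALSE]
    rownames(calls) <- NULL
  }
  if (!is.null(out)) writeCallsTsv(calls, out)
  attr(calls, "rejected") <- ver$rejected
  calls
}

#' Partition two call sets into common and set-specific insertions
#'
#' Two calls are the same insertion when their TSD spans overlap on the
#' same chromosome. Used for line-specific subtraction: calls present in a
#' derivative line but not its parent are the de novo insertions.
#'
#' @param sample,control insertion-call data.frames on the same reference.
#' @return list with `sampleSpecific` and `controlSpecific` call
#'   data.frames and `summary`, a named integer vector
#'   `(common, sample_only, control_only)` where `common` counts sample
#'   calls also present in the control.
#' @export
diffCalls <- function(sample, control) {
  toGR <- function(x) {
    if (nrow(x) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(x$chrom, IRanges::IRanges(
      pmin(x$tail_pos, x$head_pos), pmax(x$tail_pos, x$head_pos)))
  }
  # disjoint chromosome sets between the two call tables are legitimate
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(toGR(sample), toGR(control)))
  sCommon <- unique(S4Vectors::queryHits(ov))
  cCommon <- unique(S4Vectors::subjectHits(ov))
  sampleSpecific <- sample[setdiff(seq_len(nrow(sample)), sCommon), ,
                           drop = FALSE]
  controlSpecific <- control[setdiff(seq_len(nrow(control)), cCommon), ,
                             drop = FALSE]
  rownames(sampleSpecific) <- rownames(controlSpecific) <- NULL
  list(sampleSpecific = sampleSpecific, controlSpecific = controlSpecific,
       summary = c(common = length(sCommon),
                   sample_only = nrow(sampleSpecific),
                   control_only = nrow(controlSpecific)))
}
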