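# parameter sweep over signature and TSD lengths, the packaged fixture of
# validated rice Tos17 insertion loci, and summary reporting

# project TSD groups onto reference loci: map both representatives, demand
# unique placement on one chromosome with spacing consistent with the group
# TSD, then reuse the extended caller's three-way TSD verification
.groupLoci <- function(groups, index, pairWindow = 10L) {
  if (length(groups) == 0L) return(0L)
  pairs <- do.call(rbind, lapply(groups, function(g) {
    mh <- .mapOne(g@repHead, "head", index)
    mt <- .mapOne(g@repTail, "tail", index)
    if (mh$status != "unique" || mt$status != "unique") return(NULL)
    if (mh$chrom != mt$chrom) return(NULL)
    d <- abs(mh$pos - mt$pos)
    if (d >= pairWindow || d + 1L != nchar(g@tsd)) return(NULL)
    sup <- groupSupport(g)
    data.frame(chrom = mh$chrom, head_pos = mh$pos, tail_pos = mt$pos,
               distance = d, head_strand = mh$ref_strand,
               tail_strand = mt$ref_strand,
               head_support = sup[["head"]], tail_support = sup[["tail"]],
               head_flank = g@repHead, tail_flank = g@repTail,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) return(0L)
  nrow(verifyTsd(pairs, index)$calls)
}

#' Sweep signature length and TSD length
#'
#' Re-runs the scan/group stage for every combination of signature length
#' `k` and TSD length `L`, reporting how many flank records and TSD groups
#' each combination yields and — when a reference is supplied — how many
#' groups project onto a verified reference locus. Because shortening the
#' signature erodes its specificity, flank-record counts inflate at small
#' `k`; and because TSD grouping keys on exactly `L` bases, locus counts
#' collapse when `L` misses the element's true TSD length. Sweeping is how
#' an unknown TSD length is discovered with the reference-free caller.
#'
#' @param reads FASTQ path or data.frame (see [scanReads()]); a path is
#'   loaded once and reused across combinations.
#' @param te element sequence (see [signatureFromTE()]).
#' @param reference optional FASTA path / `DNAStringSet` /
#'   [RefIndex-class]; enables the `n_loci` column.
#' @param kRange signature lengths to try.
#' @param LRange TSD lengths to try.
#' @param pairWindow strict junction-distance bound for locus projection.
#' @return data.frame with one row per (k, L): `k`, `L`, `n_flanks`,
#'   `n_groups`, `n_loci` (`NA` without a reference).
#' @export
runSweep <- function(reads, te, reference = NULL, kRange = 17L,
                     LRange = 3:7, pairWindow = 10L) {
  stopifnot(length(kRange) >= 1L, length(LRange) >= 1L)
  if (is.character(reads)) reads <- readFastq(reads)
  index <- if (is.null(reference)) NULL
           else if (is(reference, "RefIndex")) reference
           else buildRefIndex(reference)
  rows <- list()
  for (k in sort(as.integer(kRange))) {
    sig <- signatureFromTE(te, k = k)
    # scan once per k at the loosest threshold, then filter per L
    allFlanks <- scanReads(reads, sig, callerParams(tsdLen = 1L),
                           mode = "basic")
    for (L in sort(as.integer(LRange))) {
      fl <- allFlanks[allFlanks$flank_len >= L, , drop = FALSE]
      groups <- lapply(groupByTsd(fl, L), selectRepresentatives)
      nLoci <- if (is.null(index)) NA_integer_
               else .groupLoci(groups, index, pairWindow)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, L = L, n_flanks = nrow(fl), n_groups = length(groups),
        n_loci = nLoci, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# md5 of the packaged fixture; guards against silent corruption
.tos17FixtureMd5 <- "13f0625b02c9bf811354fb40e51671fb"

#' Validated Tos17 insertion loci in two rice regenerant lines
#'
#' Packaged reference fixture: the published, PCR/sequencing-validated set
#' of de novo Tos17 insertion loci detected in two regenerated rice lines
#' (ttm2 and ttm5, derivatives of cv. Nipponbare), with 1-based junction
#' coordinates of the element tail and head on the reference genome, the
#' 5 bp TSD, the element orientation, which detector reported each locus,
#' and the wet-lab confirmation status. One ttm5 locus set on chr07 carries
#' a second coordinate pair (columns `tail_pos2`/`head_pos2`): two
#' insertions sharing one TSD string, the scenario that makes the
#' reference-free caller undercount by one. The fixture anchors the
#' coordinate conventions (junction order encodes orientation; TSD length
#' is junction distance + 1) and the per-line, per-detector counts.
#'
#' @return data.frame with 16 rows (17 coordinate pairs) and columns
#'   `detected_by`, `line`, `chrom`, `tail_pos`, `head_pos`, `tail_pos2`,
#'   `head_pos2`, `tsd_size`, `tsd_tail`, `tsd_head`, `direction`,
#'   `confirmed`.
#' @export
tos17Fixture <- function() {
  path <- system.file("extdata", "tos17_ttm_insertions.tsv",
                      package = "tsdcaller", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .tos17FixtureMd5))
    stop("packaged fixture checksum mismatch (", md5, "); the file ",
         "tos17_ttm_insertions.tsv has been altered", call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                   colClasses = c(chrom = "character"))
  stopifnot(nrow(df) == 16L)
  df
}

#' Expand the fixture to one row per coordinate pair
#'
#' @param fixture output of [tos17Fixture()].
#' @return data.frame with one row per junction-coordinate pair (17 rows
#'   for the packaged fixture): `detected_by`, `line`, `chrom`,
#'   `tail_pos`, `head_pos`, `tsd_size`, `tsd_head`, `direction`,
#'   `confirmed`.
#' @export
fixturePairs <- function(fixture = tos17Fixture()) {
  extra <- fixture[!is.na(fixture$tail_pos2), , drop = FALSE]
  extra$tail_pos <- extra$tail_pos2
  extra$head_pos <- extra$head_pos2
  out <- rbind(fixture, extra)
  out$tail_pos2 <- out$head_pos2 <- NULL
  rownames(out) <- NULL
  out
}

#' Summarise a call set
#'
#' Totals, per-chromosome counts and orientation breakdown, plus the
#' common/line-specific partition when a control call set is supplied.
#'
#' @param calls insertion-call data.frame.
#' @param control optional control call set (same reference) for
#'   line-specific subtraction via [diffCalls()].
#' @return an object of class `insertionSummary` (a list with elements
#'   `n_calls`, `per_chrom`, `direction`, and optionally `comparison`),
#'   printed human-readably.
#' @export
reportSummary <- function(calls, control = NULL) {
  out <- list(n_calls = nrow(calls),
              per_chrom = table(calls$chrom),
              direction = table(calls$direction))
  if (!is.null(control)) out$comparison <- diffCalls(calls, control)$summary
  class(out) <- "insertionSummary"
  out
}

#' @export
print.insertionSummary <- function(x, ...) {
  cat("Insertion calls:", x$n_calls, "\n")
  if (x$n_calls > 0L) {
    cat("  per chromosome:",
        paste(names(x$per_chrom), as.integer(x$per_chrom), sep = "=",
              collapse = ", "), "\n")
    cat("  direction:     ",
        paste(names(x$direction), as.integer(x$direction), sep = "=",
              collapse = ", "), "\n")
  }
  if (!is.null(x$comparison)) {
    cat("  vs control: common =", x$comparison[["common"]],
        "| sample-only =", x$comparison[["sample_only"]],
        "| control-only =", x$comparison[["control_only"]], "\n")
  }
  invisible(x)
}
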