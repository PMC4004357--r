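# seeded simulator: random genomes, planted TE insertions with TSDs,
# paired-end reads with substitution errors, and truth-based scoring

#' Simulate a random multi-chromosome genome
#'
#' I.i.d. bases at the requested GC content. With a seed the result is
#' reproducible; with `seed = NULL` the ambient RNG stream is used (so a
#' caller can wrap several simulation steps under one seed).
#'
#' @param lengths integer vector of chromosome lengths in bp; one
#'   chromosome per entry. Lengths of at least ~10 kb keep random 20-mers
#'   effectively unique, which flank mapping relies on.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed or `NULL`.
#' @param names chromosome names; default `chr01`, `chr02`, ...
#' @return named `DNAStringSet`.
#' @export
makeGenome <- function(lengths, gc = 0.5, seed = NULL, names = NULL) {
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L || any(is.na(lengths)) || any(lengths < 1L))
    stop("chromosome lengths must be positive", call. = FALSE)
  stopifnot(gc > 0, gc < 1)
  if (is.null(names)) names <- sprintf("chr%02d", seq_along(lengths))
  .withSeed(seed, {
    prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lengths, function(n) {
      paste(sample(names(prob), n, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1L))
    names(seqs) <- names
    Biostrings::DNAStringSet(seqs)
  })
}

# total occurrence count of a pattern in a genome, both strands
# (palindromes counted once, as in locateOccurrences)
.countBothStrands <- function(pat, seqs) {
  n <- sum(Biostrings::vcountPattern(pat, seqs, fixed = TRUE))
  rc <- revComp(pat)
  if (rc != pat) n <- n + sum(Biostrings::vcountPattern(rc, seqs, fixed = TRUE))
  n
}

#' Plant TE insertions with TSDs into a genome
#'
#' At each chosen site the pre-insertion bases `[s, e]`
#' (`e = s + tsdLen - 1`) are duplicated: the mutant carries
#' `...prefix..e | TE | s..suffix...`, i.e. left TSD + element + right TSD,
#' with the element reverse-complemented for reverse-orientation events.
#' Truth records use pre-insertion coordinates — the coordinate system the
#' callers report in.
#'
#' Sites are drawn so that the +/- `contextPad` bp context around the TSD is
#' unique in the genome (both strands), sites sit at least `minGap` bp
#' apart (so flanks are mappable and junction pairs cannot interfere), and
#' TSD strings are pairwise distinct up to reverse complement — except
#' where `sharedTsdPairs` deliberately plants collisions. `sharedTsdPairs = k` forces the last `k` sites to duplicate
#' the TSD strings (and orientations) of the first `k` sites at distant
#' loci — the TSD-collision scenario that makes the reference-free caller
#' undercount.
#'
#' @param genome pre-insertion genome (`DNAStringSet`, FASTA path or named
#'   character).
#' @param te element sequence (single sequence; length >= 2 x signature
#'   length you intend to scan with).
#' @param n total number of insertions to plant.
#' @param tsdLen TSD length in bp.
#' @param reverseFrac expected fraction of reverse-orientation insertions.
#' @param seed integer seed or `NULL`.
#' @param minGap minimum distance between sites on one chromosome (bp).
#' @param contextPad half-width of the uniqueness context (bp).
#' @param sharedTsdPairs number of planted TSD-string collisions.
#' @param maxTries sampling attempts before giving up.
#' @return list with `mutant` (`DNAStringSet`) and `truth` (data.frame:
#'   `chrom`, `tsd_start`, `tsd_end`, `orientation`, `te_name`, `tsd_seq`,
#'   sorted by locus).
#' @export
plantInsertions <- function(genome, te, n, tsdLen = 5L, reverseFrac = 0.5,
                            seed = NULL, minGap = 1000L, contextPad = 150L,
                            sharedTsdPairs = 0L, maxTries = 10000L) {
  seqs <- .asDNAStringSet(genome, "genome")
  teSet <- .asDNAStringSet(te, "te")
  if (length(teSet) != 1L) stop("te must be a single sequence", call. = FALSE)
  teName <- names(teSet)[1L]
  teStr <- as.character(teSet[[1L]])
  n <- as.integer(n)
  tsdLen <- as.integer(tsdLen)
  sharedTsdPairs <- as.integer(sharedTsdPairs)
  stopifnot(n >= 1L, tsdLen >= 1L, sharedTsdPairs >= 0L,
            sharedTsdPairs * 2L <= n)
  chromStr <- as.character(seqs)
  lens <- nchar(chromStr)

  .withSeed(seed, {
    ok <- function(ci, s, chosen, checkTsd = TRUE) {
      e <- s + tsdLen - 1L
      if (s - contextPad < 1L || e + contextPad > lens[ci]) return(FALSE)
      same <- chosen[chosen$ci == ci, , drop = FALSE]
      if (nrow(same) && any(abs(same$s - s) < minGap)) return(FALSE)
      # unless a collision is requested, sites must not share a TSD string
      # in any read orientation (i.e. distinct up to reverse complement)
      if (checkTsd && nrow(chosen)) {
        tsd <- substring(chromStr[ci], s, e)
        prev <- substring(chromStr[chosen$ci], chosen$s, chosen$s + tsdLen - 1L)
        if (canonicalTsd(tsd) %in% canonicalTsd(prev)) return(FALSE)
      }
      ctx <- substring(chromStr[ci], s - contextPad, e + contextPad)
      .countBothStrands(ctx, seqs) == 1L
    }
    chosen <- data.frame(ci = integer(), s = integer())
    nFree <- n - sharedTsdPairs
    tries <- 0L
    while (nrow(chosen) < nFree) {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("could not place ", n, " insertion sites under the gap/",
             "uniqueness constraints", call. = FALSE)
      ci <- sample.int(length(lens), 1L, prob = lens)
      s <- sample.int(lens[ci] - tsdLen + 1L, 1L)
      if (ok(ci, s, chosen)) chosen <- rbind(chosen, data.frame(ci = ci, s = s))
    }
    orientation <- ifelse(runif(nFree) < reverseFrac, "reverse", "forward")

    # TSD-collision partners: same TSD string and orientation, distant locus
    for (j in seq_len(sharedTsdPairs)) {
      tsd <- substring(chromStr[chosen$ci[j]], chosen$s[j],
                       chosen$s[j] + tsdLen - 1L)
      m <- Biostrings::vmatchPattern(tsd, seqs, fixed = TRUE)
      cand <- data.frame(
        ci = rep.int(seq_along(lens), S4Vectors::elementNROWS(m)),
        s = unlist(Biostrings::startIndex(m), use.names = FALSE))
      cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
      placed <- FALSE
      for (r in seq_len(nrow(cand))) {
        if (ok(cand$ci[r], cand$s[r], chosen, checkTsd = FALSE)) {
          chosen <- rbind(chosen, cand[r, , drop = FALSE])
          orientation <- c(orientation, orientation[j])
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place a TSD-sharing partner site for '", tsd, "'",
             call. = FALSE)
    }

    truth <- data.frame(
      chrom = names(seqs)[chosen$ci], tsd_start = chosen$s,
      tsd_end = chosen$s + tsdLen - 1L, orientation = orientation,
      te_name = teName,
      tsd_seq = substring(chromStr[chosen$ci], chosen$s,
                          chosen$s + tsdLen - 1L),
      stringsAsFactors = FALSE)
    truth <- truth[order(truth$chrom, truth$tsd_start), , drop = FALSE]
    rownames(truth) <- NULL

    teRc <- revComp(teStr)
    mutant <- vapply(seq_along(chromStr), function(ci) {
      tt <- truth[truth$chrom == names(seqs)[ci], , drop = FALSE]
      if (nrow(tt) == 0L) return(chromStr[ci])
      pieces <- character(0L)
      last <- 1L
      for (r in seq_len(nrow(tt))) {
        ins <- if (tt$orientation[r] == "forward") teStr else teRc
        pieces <- c(pieces, substring(chromStr[ci], last, tt$tsd_end[r]), ins)
        last <- tt$tsd_start[r]
      }
      paste(c(pieces, substring(chromStr[ci], last, lens[ci])), collapse = "")
    }, character(1L))
    names(mutant) <- names(seqs)
    list(mutant = Biostrings::DNAStringSet(mutant), truth = truth)
  })
}

# substitution errors at a fixed per-base rate, in place
.addErrors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  nerr <- stats::rbinom(length(reads), nchar(reads), rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(nerr > 0L)) {
    s <- reads[i]
    pos <- sample.int(nchar(s), nerr[i])
    for (p in pos) {
      substr(s, p, p) <- sample(setdiff(bases, substr(s, p, p)), 1L)
    }
    reads[i] <- s
  }
  reads
}

#' Simulate shotgun reads from a genome
#'
#' Uniform fragment start positions on both strands; i.i.d. substitution
#' errors at `errorRate` (no indels — sufficient to exercise the
#' exact-match sensitivity loss that is the caller's known failure mode).
#' Total read count is `round(coverage * genome_len / readLen)`, halved
#' per mate when paired. Qualities are constant `I`.
#'
#' @param genome `DNAStringSet` (typically a mutant genome), FASTA path or
#'   named character.
#' @param path output FASTQ path (`.gz` suffix gzips); paired mates are
#'   interleaved with `/1`, `/2` id suffixes.
#' @param readLen read length in bp (default 100).
#' @param coverage mean sequencing depth.
#' @param paired simulate paired-end fragments?
#' @param insertMean,insertSd fragment length distribution (bp), truncated
#'   below at `readLen`.
#' @param errorRate per-base substitution probability.
#' @param seed integer seed or `NULL`.
#' @return (invisibly) `path`, with the read count as attribute `"nReads"`.
#' @export
generateReads <- function(genome, path, readLen = 100L, coverage = 30,
                          paired = TRUE, insertMean = 300L, insertSd = 30L,
                          errorRate = 0, seed = NULL) {
  seqs <- .asDNAStringSet(genome, "genome")
  chromStr <- as.character(seqs)
  lens <- nchar(chromStr)
  readLen <- as.integer(readLen)
  if (readLen > min(lens))
    stop("readLen exceeds the shortest chromosome", call. = FALSE)
  nReads <- round(coverage * sum(lens) / readLen)
  nFrag <- if (paired) as.integer(round(nReads / 2)) else as.integer(nReads)

  .withSeed(seed, {
    ci <- sample.int(length(lens), nFrag, replace = TRUE, prob = lens)
    fragLen <- if (paired) {
      pmin(lens[ci], pmax(readLen, as.integer(round(
        stats::rnorm(nFrag, insertMean, insertSd)))))
    } else {
      rep(readLen, nFrag)
    }
    start <- floor(stats::runif(nFrag, 1, lens[ci] - fragLen + 1 + 1))
    frag <- substring(chromStr[ci], start, start + fragLen - 1L)
    minus <- stats::runif(nFrag) < 0.5
    if (any(minus)) frag[minus] <- revComp(frag[minus])

    if (paired) {
      r1 <- substring(frag, 1L, readLen)
      r2 <- revComp(substring(frag, fragLen - readLen + 1L, fragLen))
      reads <- as.vector(rbind(.addErrors(r1, errorRate),
                               .addErrors(r2, errorRate)))
      ids <- as.vector(rbind(sprintf("r%07d/1", seq_len(nFrag)),
                             sprintf("r%07d/2", seq_len(nFrag))))
    } else {
      reads <- .addErrors(frag, errorRate)
      ids <- sprintf("r%07d", seq_len(nFrag))
    }
    qual <- strrep("I", nchar(reads))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con), add = TRUE)
    writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
    out <- path
    attr(out, "nReads") <- length(reads)
    invisible(out)
  })
}

#' Score insertion calls against the planted truth
#'
#' A call matches a truth record iff the chromosome matches, the junction
#' pair brackets exactly the planted TSD span, the TSD sequence is
#' identical, and the reported direction equals the planted orientation.
#'
#' @param calls insertion-call data.frame ([runExtended()]).
#' @param truth truth data.frame ([plantInsertions()]).
#' @return list with `recall`, `precision`, and `matches` (the truth table
#'   with `detected` flags).
#' @export
evaluateCalls <- function(calls, truth) {
  callKey <- if (nrow(calls)) {
    paste(calls$chrom, pmin(calls$tail_pos, calls$head_pos),
          pmax(calls$tail_pos, calls$head_pos), calls$tsd_seq,
          calls$direction)
  } else character(0L)
  truthKey <- if (nrow(truth)) {
    paste(truth$chrom, truth$tsd_start, truth$tsd_end, truth$tsd_seq,
          truth$orientation)
  } else character(0L)
  detected <- truthKey %in% callKey
  matches <- cbind(truth, data.frame(detected = detected))
  recall <- if (length(truthKey)) mean(detected) else NA_real_
  precision <- if (length(callKey)) mean(callKey %in% truthKey) else NA_real_
  list(recall = recall, precision = precision, matches = matches)
}

#' Write / read a simulation truth table
#'
#' @param truth truth data.frame from [plantInsertions()].
#' @param path TSV path.
#' @return (invisibly) `path`; `readTruthTsv()` returns the data.frame.
#' @export
writeTruthTsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthTsv
#' @export
readTruthTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(chrom = "character", tsd_seq = "character"))
}

#' One-call simulation of a complete insertion experiment
#'
#' Convenience wrapper tying the simulator together under a single seed:
#' random reference, random element (whose terminal signatures are checked
#' to be absent from the reference), planted insertions, and a FASTQ of
#' reads from the mutant genome. This is the package's stand-in for a
#' resequenced derivative line.
#'
#' @param seed integer seed driving every random step.
#' @param genomeLengths chromosome lengths of the reference (bp).
#' @param nInsertions insertions to plant.
#' @param tsdLen TSD length (bp).
#' @param teLength element length (bp).
#' @param reverseFrac expected fraction of reverse-orientation insertions.
#' @param sharedTsdPairs planted TSD-string collisions (see
#'   [plantInsertions()]).
#' @param coverage,readLen,paired,errorRate read simulation settings
#'   ([generateReads()]).
#' @param sigLen signature length k for the returned [TESignature-class].
#' @param dir directory for the FASTQ (created; default a tempdir).
#' @param gc GC fraction of the reference.
#' @return list: `reference` (`DNAStringSet`), `te` (named character),
#'   `sig`, `truth`, `mutant`, `fastq` (path).
#' @export
simulateInsertionExperiment <- function(seed, genomeLengths = c(120000L, 80000L),
                                        nInsertions = 12L, tsdLen = 5L,
                                        teLength = 400L, reverseFrac = 0.5,
                                        sharedTsdPairs = 0L, coverage = 30,
                                        readLen = 100L, paired = TRUE,
                                        errorRate = 0, sigLen = 17L,
                                        dir = tempfile("simexp"), gc = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .withSeed(seed, {
    reference <- makeGenome(genomeLengths, gc = gc, seed = NULL)
    # draw an element whose terminal k-mers never occur in the reference,
    # so every signature hit in reads is a true junction
    te <- NULL
    for (try in 1:50) {
      cand <- paste(sample(c("A", "C", "G", "T"), teLength, replace = TRUE),
                    collapse = "")
      headK <- substring(cand, 1L, sigLen)
      tailK <- substring(cand, teLength - sigLen + 1L, teLength)
      if (.countBothStrands(headK, reference) == 0L &&
          .countBothStrands(tailK, reference) == 0L) {
        te <- cand
        break
      }
    }
    if (is.null(te))
      stop("could not draw an element with reference-absent termini",
           call. = FALSE)
    names(te) <- "simTE"
    planted <- plantInsertions(reference, te, n = nInsertions,
                               tsdLen = tsdLen, reverseFrac = reverseFrac,
                               seed = NULL, sharedTsdPairs = sharedTsdPairs)
    fastq <- file.path(dir, "reads.fastq")
    generateReads(planted$mutant, fastq, readLen = readLen,
                  coverage = coverage, paired = paired,
                  errorRate = errorRate, seed = NULL)
    list(reference = reference, te = te,
         sig = signatureFromTE(te, k = sigLen), truth = planted$truth,
         mutant = planted$mutant, fastq = fastq)
  })
}
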