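# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the ambient RNG stream" (callers composing several
# seeded steps wrap the whole block once instead).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

.assertDna <- function(x, allowN = TRUE, what = "sequence") {
  pat <- if (allowN) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    stop(what, " contains characters outside the DNA alphabet: ",
         paste(unique(unlist(strsplit(gsub(if (allowN) "[ACGTN]" else "[ACGT]",
                                           "", x[bad][1L]), ""))), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

# zero-row templates keep column contracts in one place
.emptyFlanks <- function() {
  data.frame(read_id = character(), side = character(),
             detected_on = character(), flank = character(),
             flank_len = integer(), stringsAsFactors = FALSE)
}

.emptyCalls <- function() {
  data.frame(chrom = character(), tail_pos = integer(), head_pos = integer(),
             tsd_len = integer(), tsd_seq = character(), direction = character(),
             head_support = integer(), tail_support = integer(),
             stringsAsFactors = FALSE)
}

.emptyClusters <- function() {
  data.frame(chrom = character(), side = character(), pos = integer(),
             ref_strand = character(), support = integer(),
             rep_flank = character(), rep_read_id = character(),
             stringsAsFactors = FALSE)
}

# coerce FASTA path / DNAStringSet / named character to a named DNAStringSet
.asDNAStringSet <- function(x, what = "sequences") {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("^[ACGTN]+$", x)) {
    return(readFasta(x))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(Biostrings::DNAStringSet(toupper(x)))
  }
  if (is(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  if (!is(x, "DNAStringSet")) {
    stop(what, " must be a FASTA path, character vector or DNAStringSet",
         call. = FALSE)
  }
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

# canonical form of a TSD string: lexicographic min of string and revcomp,
# the orientation-free identity used when comparing reference-free and
# reference-based TSD reports
canonicalTsd <- function(tsd) {
  rc <- revComp(tsd)
  ifelse(tsd <= rc, tsd, rc)
}
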