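# tsdcaller

Detection of de novo transposable element (TE) insertions from raw short
reads, using the target site duplication (TSD) that most LTR
retrotransposons and TIR DNA transposons leave behind when they insert.

## The problem and the method

Calling new TE insertions from short reads is hard precisely because the
element sequence is repetitive: a read-mapping-first pipeline cannot place
reads that consist mostly of TE. `tsdcaller` inverts the logic. An
insertion duplicates a short target site (5 bp for the rice retrotransposon
Tos17, 8 bp for the Drosophila P-element), so reads that span a junction
contain (i) the first or last *k* bases of the element — its **head** or
**tail** signature (*k* = 17 by default) — and (ii) a genomic **flank**
that *ends* (head side) or *begins* (tail side) with the TSD.

Reads and their reverse complements are scanned for exact signature
occurrences, and the flanks are resolved into insertions by one of two
callers:

* **Basic (reference-free)** — `runBasic()`. Head flanks are grouped with
  tail flanks sharing the same length-*L* TSD string; the longest flank
  pair represents each group. Needs the TSD length *L*, but no reference
  genome, so it also works for insertions inside repetitive regions. Two
  insertions that happen to duplicate the same string merge into one group;
  for independent sites this occurs with probability 4^-L per pair
  (1/1024 for L = 5, `tsdCollisionProb()`).
* **Extended (reference-based)** — `runExtended()`. Each flank is placed on
  the reference only if it matches exactly, full-length, at a single
  genomic location (either strand). Head and tail junctions within a strict
  10 bp window are paired, and a pair is called only when head flank, tail
  flank and reference agree letter-for-letter on the duplicated site. Needs
  a reference, but no TSD length — the TSD is read off the junction
  spacing (`tsd_len = |head - tail| + 1`), and the coordinate order gives
  the element orientation (head downstream of tail = forward).

A seeded simulator (`makeGenome()`, `plantInsertions()`,
`generateReads()`, `simulateInsertionExperiment()`) plants insertions with
known TSDs in both orientations and scores calls against the truth
(`evaluateCalls()`), so every claim the package makes is testable offline.
A curated fixture of wet-lab-validated Tos17 insertion loci in two rice
regenerant lines (`tos17Fixture()`) anchors the coordinate conventions.

## Worked example

```r
library(tsdcaller)

# 50 kb two-chromosome genome, 3 planted insertions, 30x error-free reads
sim <- simulateInsertionExperiment(seed = 5, genomeLengths = c(30000, 20000),
                                   nInsertions = 3)
calls <- runExtended(sim$fastq, sim$sig, sim$reference)
calls
#>   chrom tail_pos head_pos tsd_len tsd_seq direction head_support tail_support
#> 1 chr01     5859     5855       5   ACACA   reverse           26           10
#> 2 chr01    10797    10801       5   CTGAA   forward           25           27
#> 3 chr02    18028    18032       5   AACAG   forward           19           20

unlist(evaluateCalls(calls, sim$truth)[c("recall", "precision")])
#>    recall precision
#>         1         1

groupsTable(runBasic(sim$fastq, sim$sig, 5))[, "tsd"]
#> [1] "AACAG" "CTGAA" "TGTGT"
```

Each call row is one insertion: the 1-based junction coordinates of the
element tail and head on the (pre-insertion) reference, the TSD length and
sequence they bracket, the orientation implied by their order (row 1:
head < tail, a reverse-orientation event), and the number of reads
supporting each junction. Both callers recover all three planted
insertions; note the reference-free caller reports the reverse-orientation
event's TSD in read orientation (`TGTGT` = reverse complement of `ACACA`),
since without a reference there is no plus strand to normalise to.

A shell front end with `simulate`, `basic`, `extended`, `sweep`, `diff`
and `fixture-check` subcommands is installed at
`system.file("scripts", "tsdcaller.R", package = "tsdcaller")`.

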