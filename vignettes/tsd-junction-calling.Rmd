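---
title: "Calling de novo TE insertions from TSD-bearing junction reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling de novo TE insertions from TSD-bearing junction reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsdcaller)
```

## The insertion model

When an LTR retrotransposon or a TIR DNA transposon integrates, the
staggered cut at the target site is repaired into a short direct
duplication: the same 1–10 bp string (the target site duplication, TSD)
ends up immediately 5' **and** 3' of the inserted element. Elements
without TSDs (non-LTR class I elements) are outside this package's scope —
the whole method keys on the duplication.

A short read that spans a junction therefore decomposes into a genomic
*flank* and a prefix or suffix of the element. We detect the element part
by its terminal *signature*: the first *k* bases (head, 5') or last *k*
bases (tail, 3'), held in a `TESignature`. On the plus strand of a
*forward* insertion whose pre-insertion duplicated site is `[s, e]`
(`e = s + L - 1`):

* a read crossing the left junction ends its genomic flank at `e`, just
  before the element head — so the head flank's *suffix* of length `L` is
  the TSD, and the head junction coordinate is `e`;
* a read crossing the right junction starts its genomic flank at `s`,
  just after the element tail — the tail flank's *prefix* is the TSD, and
  the tail junction is `s`.

For a reverse-orientation insertion the same geometry holds on the minus
strand, which swaps the junction order. That single fact makes orientation
inference free: `head > tail` is forward, `head < tail` reverse, and
`|head - tail| + 1` is the TSD length (`tsdFromJunctions()`). All
coordinates in the package are 1-based inclusive, on the pre-insertion
reference; equal coordinates (a degenerate 1 bp TSD) are reported forward
by convention so the function is total — the elements this method targets
never produce that case.

Scanning (`scanRead()`, `scanReads()`) searches the read *and* its reverse
complement with forward-strand rules, so emitted flanks are always
oriented head-flank-ends-at-junction / tail-flank-starts-at-junction
regardless of which strand was sequenced. Matching is **exact**:
signatures reject ambiguity codes, and a read with an `N` or a
substitution inside the matched window simply does not match. This is a
deliberate, documented sensitivity/specificity trade: a single spontaneous
mutation in an element terminus silently costs the affected locus, which
is why signature length is a tunable worth sweeping (below), and why the
simulator's error model is substitution-only — it exercises exactly this
failure mode.

## The two callers

**Reference-free (`runBasic()`).** Head flanks are keyed by their
length-*L* suffix, tail flanks by their length-*L* prefix
(`groupByTsd()`); keys present on both sides become `TSDGroup`s and the
longest flank on each side is the group's representative
(`selectRepresentatives()`, ties broken by smallest read id so output is
invariant to read order). One-sided keys are dropped by default: evidence
on a single side cannot be told apart from a chance signature hit. The
group FASTA (`writeGroupFasta()`) is sorted by TSD and ready for any
downstream aligner. Two caveats are intrinsic: (i) distinct insertions
sharing one TSD string merge — groups are identities, not loci; with
TSD length *L* the per-pair collision probability is 4^-L
(`tsdCollisionProb()`); (ii) the TSD is reported in *read orientation*:
for a reverse-orientation insertion that is the reverse complement of the
plus-strand site, and without a reference no normalisation is possible.
`canonicalTsd()` provides the orientation-free form under which the two
callers' TSD sets are comparable.

**Reference-based (`runExtended()`).** Flanks of at least `minFlankMap`
(20 bp) are placed on the reference by `mapFlank()`: an exact, full-length
match required at **exactly one** genomic location over both strands.
There is no mismatch tolerance, no clipping, and no best-hit heuristic —
a flank whose sequence recurs identically elsewhere is rejected as
multi-mapped rather than guessed at. We chose this contract over a
BLAST-like scoring search deliberately: top-hit heuristics are version-
and parameter-sensitive, while an exactness-plus-uniqueness rule is
reproducible bit-for-bit and its failure mode (silence, with a reason) is
the safe one. The cost is insertions inside long perfect repeats, which
are unreachable by any unique-placement method. The matching itself is
delegated to Biostrings; a naive full-scan matcher written independently
in the test suite must agree with `mapFlank()` on every flank, match or
rejection.

Placed junctions collapse per (chromosome, side, position) into clusters
(`clusterJunctions()`, support = read count, representative = longest
flank). Head/tail clusters on one chromosome pair when their distance is
**strictly** under `pairWindow` = 10 bp (`pairJunctions()`) — the bound is
exclusive, so distance 9 pairs and distance 10 does not, and since
TSD length is distance + 1 this admits TSDs up to 10 bp, matching the
biology of TSD-generating elements. A candidate pair becomes a call only
after three-way verification (`verifyTsd()`): the head representative's
suffix, the tail representative's prefix (each reverse-complemented to the
plus strand when its flank was placed on the minus strand) and the
reference substring over the junction span must be identical. Any one
consistent read pair suffices — support thresholds beyond 1 are the
caller's to raise (`--min-support` style filtering on the emitted
`head_support`/`tail_support` columns) — and all verified pairs are
emitted even when a cluster pairs twice inside the window, verification
being what makes spurious combinations improbable. One consequence worth
stating: direction comes purely from coordinate order, never from strand
bookkeeping, and the packaged fixture of validated rice loci
(`tos17Fixture()`) confirms that rule on all 17 published junction pairs.

`diffCalls()` subtracts a control call set (overlap of TSD spans on the
same chromosome) for line-specific insertion discovery, and `runSweep()`
re-runs scan/group/locus-projection over a grid of (*k*, *L*): flank
counts inflate as *k* shrinks below the element-specificity threshold,
and verified locus counts collapse when *L* misses the true TSD length —
the sweep is how an unknown TSD length is discovered reference-free.

## The simulator: what it emulates, and what it does not

`simulateInsertionExperiment()` stands in for a resequenced derivative
line: an i.i.d. random reference (default two chromosomes, 200 kb total,
GC 0.5), a random 400 bp element whose 17 bp termini are verified absent
from the reference, 12 planted insertions with 5 bp TSDs in both
orientations, and error-free 100 bp paired-end reads at 30x — sizes chosen
to mirror, at desk scale, the regenerant-line setting the method was
designed for (a handful of new insertions of a ~4 kb element per line,
100 bp paired-end sequencing). Planting duplicates the site exactly as the
biology does (`prefix..e | TE | s..suffix`), records truth in
pre-insertion coordinates, and constrains sites to have unique ±150 bp
context, ≥1 kb spacing, and pairwise-distinct (up to reverse complement)
TSD strings — except where `sharedTsdPairs` plants a deliberate collision
to reproduce the basic caller's undercount. Defaults for read simulation
(insert 300 ± 30 bp, substitution-only errors, uniform starts on both
strands) are conventional short-read values.

What passing these simulations demonstrates: exact parameter recovery
(coordinates, TSD sequence, orientation, recall = precision = 1) under the
stated conditions, the strict window semantics, the collision mechanism,
and robustness of precision to 0.5% substitution noise. What they do
*not* demonstrate: performance on real genomes with repeat families,
indel and quality-structured error profiles, PCR duplicates, coverage
bias, heterozygous insertions, or an element already present in the
reference (whose own junctions appear in every sample and must be handled
by control subtraction). The simulator makes no attempt at those, and
claims about real data should be calibrated accordingly.

## Numerical and design choices

* **Signature length k = 17, minimum 8.** 17 bp terminal sequences are
  long enough to be effectively unique in host-genome-sized sequence yet
  leave ≥80 bp of flank in a 100 bp read; the class invariant `k ≥ 8`
  keeps the chance hit rate per 100 bp read below ~10^-3 even for small
  genomes.
* **Flank thresholds.** Basic mode keeps flanks ≥ L (the flank must
  contain the whole TSD — shorter carries no grouping information);
  extended mode maps flanks ≥ 20 bp, at which length a random match in a
  200 Mb genome is improbable (4^-20 ≈ 10^-12 per position) and
  uniqueness does the rest.
* **Duplicate reads are not collapsed**; support counts are raw read
  evidence.
* **Reads are treated independently** — mate pairing is not used, so the
  caller works identically on single-end data.
* **Determinism.** Groups are sorted by TSD, calls by locus,
  representatives tie-broken by read id; every simulator function accepts
  a seed (or inherits the ambient RNG stream when composed under one), so
  fixed inputs give byte-identical outputs.
* **Degenerate inputs.** Empty read sets, streams without matches, empty
  group lists and empty call tables all flow through to empty (but
  well-formed) outputs; malformed FASTQ records fail with the offending
  line number; the packaged fixture is checksummed at load.
* **Memory.** FASTQ is streamed in bounded chunks (`fastqApply()`); only
  flank records, never reads, accumulate.

## Known limitations

Exact signature matching misses loci whose element terminus carries even
one mutation (mitigate by shortening *k*, at a flank-count cost the sweep
makes visible). Unique-placement mapping cannot call insertions inside
perfect repeats longer than the flanks. The basic caller conflates
TSD-string collisions and reports read-orientation TSDs. TSD-less
elements are out of scope. Test-suite and acceptance problem sizes
(30–200 kb genomes, 15–30x) were chosen as the smallest at which all of
the above properties are statistically unambiguous; they are stated in
each test and in `scripts/acceptance.R`.
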