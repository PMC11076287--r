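---
title: "pasmap methods: 3' end classification and antisense complementarity mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pasmap methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasmap)
```

# Scope

pasmap implements two desk-scale sequence analyses that together
characterise a transcriptome's 3' ends and the base-pairing potential
within a pool of long noncoding RNAs (lncRNAs):

1. **PAS/DSE classification.** Most polyadenylated transcripts carry a
   polyadenylation signal (PAS) hexamer — consensus `AATAAA` — near the
   3' terminus, often accompanied by a T/G-rich downstream sequence
   element (DSE) past the cleavage site. Scanning the terminal window
   of every annotated transcript and summarising per gene class (mRNA
   vs lncRNA) quantifies how much less frequently lncRNAs carry
   canonical 3'-processing signals.
2. **Antisense complementarity mapping.** lncRNAs that co-localise in
   nuclear structures may do so partly through RNA:RNA hybridisation.
   Decomposing each pool sequence into k-mers (k = 19–25) and matching
   them against every pool member on both strands, tolerating 0–2
   mismatches, finds the antisense (reverse-complement) regions that
   could pair, which are then merged into candidate interaction sites.

Both stages are exercised end to end by a seeded synthetic-data module
with exact ground truth.

# The PAS model

## Variant table

The unit of matching is a 6-mer from a configurable variant table
(`pas_variant_table()`). Each variant carries

* `consensus_distance` — Hamming distance to `AATAAA`, computed, never
  configured;
* `usage_rank` — its rank in observed genome-wide usage (1 = most
  used), taken from the classical poly(A)-signal usage surveys.

The packaged default is the familiar 13-hexamer list (`AATAAA`,
`ATTAAA`, `TATAAA`, `AGTAAA`, `AAGAAA`, `AATATA`, `AATACA`, `CATAAA`,
`GATAAA`, `AATGAA`, `TTTAAA`, `ACTAAA`, `AATAGA`). Twelve are single
substitutions of the consensus; `TTTAAA` sits at distance 2 — the
table supports any distance, and the file
(`inst/extdata/pas_variants.tsv`) is plain configuration that users can
replace.

## Filtering

The search set keeps transcripts **longer than** `min_len` (default
200 nt — the boundary value is excluded, matching the conventional
definition of an lncRNA as > 200 nt) whose terminal window (default
50 nt) — and downstream window, when one is available — contain only
`A/C/G/T`. Ambiguity codes elsewhere in the transcript are harmless
and do not exclude it. Excluded records are returned as explicit call
rows with a reason (`short`, `ambiguous_window`), so every later
denominator is auditable.

## Scanning and assignment

`scan_pas_window()` reports *every* occurrence of *every* table
hexamer whose six bases lie entirely inside the terminal window —
overlapping occurrences included, sense strand only. A hexamer
partially overhanging the window boundary does not count: we read
"within the last 50 nucleotides" in its strictest sense.

When a transcript shows several variants, `assign_pas()` picks the hit
minimising `(consensus_distance, usage_rank)` lexicographically. Two
natural verbalisations of this rule — "the variant closest to
consensus" and "the most commonly used variant" — coincide whenever
the consensus itself is present, because `AATAAA` is both closest (distance
0) and most used (rank 1); the lexicographic key makes the remaining
tie-breaks explicit and order-independent. `NONE` is assigned only
when there are no hits at all.

## Gene-level reduction and percentages

Genes with several transcripts are reduced to their **best
transcript**: the same lexicographic key, with `NONE` ranked last.
`summarize_pas_by_class()` then reports, per gene class, per-variant
gene percentages plus the no-PAS percentage; the categories are
exclusive and sum to 100 within rounding (one decimal by default).
The denominator is the set of genes that survived the filters, not all
annotated genes — filtering precedes searching, so unsearchable genes
cannot meaningfully contribute to either numerator or denominator.
Tandem arrangements (two or more distinct hit start positions in one
window, counted by `count_tandem()`) and DSE presence are reported as
additional per-class percentages.

# The DSE model

The DSE is described by a position frequency matrix (sequence logo).
The matching rule is deliberately a **hard threshold**, not a log-odds
score: position *i* of the pattern allows exactly the bases whose
frequency at *i* is ≥ `threshold` (default 0.10, i.e. "seen 10% or
more of the time"), and a window position matches when every pattern
position is satisfied. `scan_dse()` realises the pattern as a regex of
per-position character classes inside a lookahead, so overlapping
matches are all reported. Lowering the threshold can only grow the
allowed sets, hence hit sets are monotone — a property the tests
assert.

The packaged logo (`inst/extdata/dse_logo_synthetic.tsv`) is a
**synthetic stand-in**: an 8-position T/G-rich matrix with the
qualitative shape of published DSE logos. It exists so the pipeline
runs out of the box; analyses of real data should supply the logo
matrix of record as a 4-column file.

Downstream windows are taken from the genome, not the transcript: for
a plus-strand gene span, the `n` bases after the span end; for a
minus-strand span, the reverse complement of the `n` bases before the
span start — both returned in the transcript's reading orientation.
Windows truncated by a chromosome edge are returned short and flagged
rather than dropped; the caller decides their fate.

# The complementarity model

## Mismatch semantics

A k-mer at query offset *i* matches target position *p*

* on `+` when `Hamming(kmer, target[p, p+k))` ≤ `max_mm`;
* on `−` (antisense) when `Hamming(kmer, rc(target[p, p+k)))` ≤
  `max_mm`,

with **full-length Hamming distance, no indels**, and every valid
position reported. End-to-end counting is exactly reproducible and
matches the ungapped-alignment mode of the short-read mappers
traditionally used for this kind of search; seed-based heuristics are
deliberately avoided. k-mers containing ambiguity codes never match
(mismatch counting over ambiguity codes is undefined); ambiguous
target bases count as mismatches.

Antisense means the query fragment pairs with the target's sense
strand as RNA:RNA duplexes do, which is why `−` hits are the default
output (`filter_antisense()`); sense hits indicate shared identical
sequence instead and can be kept with `antisense_only = FALSE`.

Self-pairs are excluded by default; with `include_self = TRUE`
(hairpin search) the degenerate exact sense self-match of a k-mer at
its own coordinates is still always removed, as it is an artifact of
querying a pool that contains the query.

The inner scan is a small compiled kernel (early-exit Hamming count
over all position pairs). An independent, deliberately naive R
scanner (`naive_scan_pool()`, vectorised per-position counting with no
early exit and no shared code) serves as the reference in the test
suite — the two routes are kept separate so that each checks the
other.

## Regions and interactors

Antisense hits for one (query, target) pair whose target intervals
overlap or are book-ended (gap 0) are unioned by `merge_regions()`
(interval arithmetic via IRanges), recording the supporting hit count
and minimum mismatch count. `summarize_interactors()` collapses the
regions into one row per ordered pair — the table of predicted
pairwise interactors. BED6 output uses 0-based half-open coordinates
throughout, name `queryID|k|mm`, the mismatch count as score, and
deterministic (target, start, name) ordering.

# The synthetic worlds

## Transcript sets

`generate_transcripts()` draws i.i.d. background at a configurable
base composition, then plants PAS hexamers uniformly inside the
terminal window at per-variant, per-class rates. The default rates
emulate the headline class difference this analysis is designed to
detect — consensus `AATAAA` in 60% of mRNA genes but only 23% of
lncRNA genes, with a thinner tail of degenerate variants in lncRNAs —
on 2000 transcripts per class, lengths uniform on 500–2000 nt.

Two construction details make recovery exact rather than approximate:

* every terminal window is rejection-sampled (bounded at 1000
  attempts) to be free of *all* table hexamers before planting — the
  stated requirement is only "no accidental consensus in unplanted
  records", but extending it to all variants means an unplanted record
  can never be assigned anything and a planted record is assigned
  exactly its planted variant, so the only error left in rate recovery
  is the binomial noise of the planting coin itself;
* downstream windows are likewise sampled free of DSE-pattern matches
  before optional planting (rate `dse_rate`, independent of PAS
  planting, so joint rates test as a product).

Deliberately short records (≤ 200 nt) and records with an `N` injected
into the terminal window are generated at configurable rates to
exercise the filter; the truth ledger marks them, and the filter must
exclude exactly those.

What the generator does **not** emulate: real base composition and
repeat structure, multi-transcript genes, 3'-UTR A-richness (which
inflates accidental variant hits in real data), or any coupling
between PAS and DSE presence. A green recovery test therefore
establishes the correctness of the scanning/assignment machinery, not
the biological calibration of real-genome percentages.

## Complement pools

`generate_complement_pool()` plants, for each configured block, the
reverse complement of a query segment into a target sequence with
**exactly** `d` substitutions (`mutate_block()` guarantees the exact
Hamming distance). Two further devices make the planted world fully
predictable:

* **central mismatches** — substitutions are confined to block
  positions contained in *every* window overlapping the block by ≥ 18
  bases, so each of the block's k-sub-windows (k = 19–25) carries
  exactly `d` mismatches and the block is found iff `max_mm ≥ d`, with
  the sliding-window count `L − k + 1` of antisense k-hits per
  direction;
* **mismatch guards** — the three target bases flanking each side of
  the planted block are rewritten so they cannot pair with their query
  counterparts; partially overlapping windows then carry at least
  `d + 1` mismatches and cannot blur the block's exact coordinates at
  `max_mm = d`.

Finally the whole pool is certified with the brute-force oracle at
k = 19 (any match of length ≥ 19 within 2 mismatches contains a 19-mer
match within 2 mismatches, so k = 19 cleanliness covers all k), level
by level for `max_mm` 0..2; pools with accidental background matches
are resampled, bounded at 1000 attempts. Hairpin plants
(query = target) are not supported by the generator — the mapper's
`include_self` path is tested with hand-built hairpins instead.

# Numerical and interface choices

* Coordinates are 0-based half-open internally and in BED; FlyBase
  header locations (`loc=chrom:start..end`, with `complement(...)` /
  `join(...)` forms; 1-based inclusive) are converted on parse. The
  header dialect is an explicit flag, never sniffed.
* The length filter is strict (`> 200`), and the logo threshold is
  inclusive (`≥ 0.10`), both following the natural reading of their
  definitions; boundary cases are pinned by tests.
* Logo rows must sum to 1 within 1e-6; a logo position where no base
  reaches the threshold is an error naming the position.
* Percentages are reported to one decimal; comparisons against
  integer-printed reference values should round to the nearest
  integer.
* All generator randomness flows from one mandatory integer seed
  through an isolated RNG scope (`withr::with_seed`); no global state
  is disturbed, and identical seeds give byte-identical outputs.
* Exit codes of the `exec/pasmap` wrapper: 0 success, 2 usage or
  configuration error, 1 runtime error.

# Known limitations

* The mapper is quadratic (all k-mers × all positions); it is meant
  for desk-scale pools (tens of sequences, kilobases each), not
  genome-scale screens.
* No gapped alignment and no thermodynamic duplex scoring: a merged
  antisense region is a candidate pairing site, not a folding
  prediction.
* Per-gene reduction uses the best transcript; if a canonical-isoform
  convention is preferred, reduce before calling and pass one
  transcript per gene.
* The packaged DSE logo is a stand-in; per-position frequencies of a
  real logo will change DSE percentages substantially, though not the
  machinery.
* Whether downstream windows should come from genomic coordinates
  even when the annotated 3' end abuts another feature is left to the
  caller; the package extracts exactly the window requested and flags
  truncation at chromosome edges.
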