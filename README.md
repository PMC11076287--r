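# pasmap

Polyadenylation-signal scanning and antisense complementarity mapping
for transcript 3' ends.

## The problem

Long noncoding RNAs (lncRNAs) are, as a class, processed differently
from mRNAs at their 3' ends: many lack the canonical polyadenylation
signal (PAS, consensus `AATAAA`) and the T/G-rich downstream sequence
element (DSE), which bears on whether they are polyadenylated at all
and on how well poly(A)-selected sequencing detects them. Separately,
lncRNAs that co-localise in nuclear structures may interact through
direct RNA:RNA base pairing, detectable as antisense
(reverse-complement) sequence matches between them.

pasmap implements both analyses as a tested, reusable R package:

* **3' end classification** — scan the last *w* nucleotides (default
  50) of every transcript for PAS hexamer variants; when several are
  found, assign the one closest to consensus (ties broken by usage
  rank); match DSEs in genome-derived downstream windows as
  per-position character classes from a sequence logo thresholded at a
  frequency cutoff (default 10%); summarise per gene class, per gene.
* **Antisense complementarity mapping** — decompose every pool
  sequence into its sliding-window k-mers (k = 19–25; a sequence of
  length L yields L − k + 1 of them), match each k-mer against every
  pool position on both strands by full-length Hamming distance with
  0–2 allowed mismatches, keep antisense matches, write BED6, and
  merge hits into candidate interaction regions per sequence pair.
* **Synthetic data with ground truth** — seeded generators plant PAS
  and DSE motifs at controlled rates and antisense blocks with *exact*
  mismatch counts, so every stage is verifiable end to end.

Formally, a k-mer `x` of query Q at offset i hits target T at position
p on the antisense strand when `d_H(x, rc(T[p, p+k))) ≤ m`, where
`d_H` is Hamming distance, `rc` reverse complement, m the mismatch
allowance; sense hits replace `rc(T[p, p+k))` with `T[p, p+k)`. The PAS
assignment rule is `argmin over window hits of
(consensus_distance, usage_rank)`.

## Worked example

```r
library(pasmap)

## 3' end classification on a synthetic two-class transcript set
cfg   <- synth_transcript_config(n_per_class = 500, seed = 42)
sim   <- generate_transcripts(cfg)
calls <- call_pas(sim$records, downstream_windows = sim$downstream)
s     <- summarize_pas_by_class(calls)
subset(s$by_variant, n_genes > 0 | variant == "NONE")
#>    gene_class variant n_genes percent
#> 1      lncRNA  AATAAA     105    21.0
#> 2      lncRNA  ATTAAA      38     7.6
#> 3      lncRNA  TATAAA      15     3.0
#> 14     lncRNA    NONE     342    68.4
#> 15       mRNA  AATAAA     290    58.0
#> 16       mRNA  ATTAAA      89    17.8
#> 17       mRNA  TATAAA      21     4.2
#> 28       mRNA    NONE     100    20.0
```

The generator plants `AATAAA` in 60% of mRNAs but 23% of lncRNAs (its
default world); the recovered 58.0% and 21.0% differ from the planted
rates only by binomial sampling noise, and each class column sums
to 100 — the assignment categories are exclusive.

```r
## antisense complementarity on a pool with planted blocks
pcfg <- pool_synth_config(n_seqs = 4, len_range = c(300L, 500L),
                          blocks = data.frame(query = c(1L, 2L),
                                              target = c(2L, 3L),
                                              length = c(25L, 30L),
                                              d = c(0L, 2L)),
                          seed = 42)
pool    <- generate_complement_pool(pcfg)
hits    <- filter_antisense(map_pool(pool$pool, 19:25, max_mm = 2))
regions <- merge_regions(hits)
summarize_interactors(regions)
#>     query_id  target_id n_regions total_bp min_mismatches
#> 1 SYNPOOL_01 SYNPOOL_02         1       29              0
#> 2 SYNPOOL_02 SYNPOOL_01         1       29              0
#> 3 SYNPOOL_02 SYNPOOL_03         1       30              2
#> 4 SYNPOOL_03 SYNPOOL_02         1       30              2
```

Each planted block appears as one merged region in both directions
(antisense complementarity is symmetric), `total_bp` spanning the
planted 25-/30-mer plus the flanking overlap of the merged k-mer hits,
and `min_mismatches` reporting the exact planted mismatch count.

## Command line

A thin wrapper over the same functions:

```sh
pasmap pas --mrna dmel-all-transcript.fasta --lncrna dmel-all-ncRNA.fasta \
       --genome dmel-all-chromosome.fasta --dialect flybase --out out/pas
pasmap complement --pool yloop_lncRNAs.fa --k 19:25 --max-mismatch 2 --out out/comp
pasmap simulate --type transcripts --seed 7 --out out/sim
```

Outputs are TSV tables, BED6 hit files and a deterministic run log.
`scripts/reproduce_flybase.R` (network required) downloads the pinned
FlyBase r6.51 bulk FASTA files and runs `cmd_pas()` with defaults on
the real annotation.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full analysis from scratch at the given seed: it
generates the synthetic two-class transcript set (2000 per class) and
a planted complement pool, runs the PAS/DSE pipeline and the antisense
mapping pipeline on them through the package's public entry points,
prints the per-class overview and interactor tables, and writes its
JSON result file to `--out`.
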