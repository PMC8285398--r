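# poisedR

Poised enhancers (PEs) are distal regulatory elements of major developmental
genes that are bookmarked in pluripotent cells before they become active:
they show open chromatin (ATAC/p300) and H3K4me1 like active enhancers, but
carry Polycomb-associated H3K27me3 instead of H3K27ac, sit near orphan CpG
islands, and often already touch their target promoters in 3D. `poisedR` is
an R toolkit for the computational side of studying these elements from
epigenomic peak sets, aimed at regulatory-genomics analysts who have peak
calls, loop lists and contact matrices in hand and want a tested, scriptable
pipeline rather than a pile of one-off bedtools invocations.

The package covers five analysis layers, each usable on its own:

* **Rule-based enhancer classification.** Per cell state ("context"), open
  chromatin peaks (fold enrichment ≥ 4, q ≤ 0.05) overlapping both H3K4me1
  and H3K27me3 broad peaks (fold ≥ 2, q ≤ 0.1, extended ±1 kb) are poised
  candidates; H3K27ac replaces H3K27me3 for active enhancers; H3K4me1 alone
  defines primed. Contexts are combined by union, TSS-proximal elements
  (±5 kb) are removed, elements overlapping the excluded mark in *any*
  context are discarded, and the survivors are merged:

      poised = merge( subtract( tss_filter( ∪_ctx ATAC ∩ K27me3 ∩ K4me1 ), K27ac_∪ ) )

  Variants implement the in vivo epiblast rule (no H3K4me1, p-value filters)
  and the cross-species de novo rule (±2.5 kb extensions, strictly >10 kb
  from any TSS), plus PoiAct relabeling for poised elements that gain
  H3K27ac in a later cell state. Class conflicts resolve as in the source
  pipelines: poised/active and poised/primed overlaps are dropped from both,
  active∩primed becomes active.

* **Chain-based conservation.** A UCSC liftOver chain parser and mapper score
  each element by its *mapped ratio* — the fraction of its bases inside
  aligned blocks of the best-scoring chain (the `liftOver -minMatch`
  semantic). `conservation_fraction()` applies an inclusive threshold
  (default 0.5) and `threshold_sweep()` profiles 0.2–0.99.

* **Association statistics.** Nearest-CGI distance profiles and exact-overlap
  percentages, promoter chromatin states (bivalent / H3K27me3-only /
  H3K4me3-only / unmarked from TSS-window mark overlap), a two-sided Fisher
  exact test written against the hypergeometric definition (cross-product
  odds ratio `(ad)/(bc)`), Wilcoxon rank-sum comparisons with mean fold
  changes, Polycomb-domain calling (replicate-intersected EED × RING1B), and
  nearest-gene assignment.

* **Loop topology.** BEDPE loop lists with significance columns are
  filtered (`p ≤ 0.01` by default), size-binned (0–300 kb–1 Mb–∞),
  hierarchically annotated against seed elements with ±10 kb anchor
  extensions (promoter TSS ±7.5 kb > other seed element > PcG domain >
  other), classified intra/inter-TAD by anchor midpoints, and compared
  between conditions by extended-anchor loop matching.

* **Contact pileups.** Sparse COO contact matrices (5 kb bins by default)
  support coverage normalization and Knight–Ruiz balancing; `pileup()`
  averages ±250 kb snippets around anchor pairs against an expected
  (per-diagonal) or shifted control, and `loopiness()` reports the center
  pixel over the mean of the four corner pixels — >1 means the pairs loop.

A seeded synthetic-data generator (`simulate_all()`) plants all of the above
— enhancer classes with their mark signatures, mapping ratios, promoter
states, loop categories and TAD statuses, contact-matrix enrichments — and
emits the exact file formats the pipeline reads plus a JSON truth manifest,
so every stage is validated by exact planted recovery.

## Worked example

```r
library(poisedR)
report <- run_all("pe_run", seed = 7)
```

This simulates a 20 Mb two-chromosome genome with 200 planted enhancers,
writes the inputs under `pe_run/inputs/`, reads them back through the
package's own parsers and runs every stage, logging to stderr:

```
[simulate] inputs written to pe_run/inputs (2.75s)
[call-enhancers] poised=60 active=60 primed=50 poiact=30 (4.63s)
[conserve] fraction@0.50 = 0.6667 (4.79s)
[loops] significant=80 intra=0.50 (5.54s)
[associate] bivalent OR=10.109 p=2.57e-09 (5.64s)
[pileup] loopiness=4.853 (planted 5) (5.99s)
```

Reading the lines in order: the classifier recovered all 200 planted
elements with their planted classes (60 poised, 60 active, 50 primed, 30
PoiAct — no spurious calls); two thirds of the poised/PoiAct set is
conserved at mapping ratio 0.5, matching the planted ratio mixture; 80 of
100 loops survive the p ≤ 0.01 filter and half are intra-TAD; promoters
looping to poised enhancers are strongly enriched for the bivalent state
(odds ratio 10.1); and the contact-matrix pileup over the planted anchor
pairs reads out a loopiness of 4.85 against a planted 5-fold center
enrichment. `pe_run/report.json` holds the same numbers machine-readably,
next to the per-stage BED/TSV outputs.

A thin CLI wraps the same calls:

```sh
Rscript inst/scripts/pe-pipeline.R run-all --outdir pe_run --seed 7
```

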