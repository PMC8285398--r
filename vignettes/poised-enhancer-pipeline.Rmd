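---
title: "Methods: poised-enhancer classification, conservation and loop topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poised-enhancer classification, conservation and loop topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, rules and numerical choices behind
`poisedR`, in the spirit of a methods section: what each stage assumes, which
parameters matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open.

## Coordinate model

All text formats the package touches (BED, narrowPeak/broadPeak, bedGraph,
BEDPE, UCSC chain, sparse COO) use 0-based half-open coordinates, and the
package preserves those semantics: bookended intervals share no base and do
not intersect. Internally, intervals live in `GRanges` (1-based closed), the
canonical container in the R genomics stack, with conversion confined to the
reader/writer boundary. Reimplementing interval algebra would have been both
wasteful and riskier than wrapping `GenomicRanges`; the test suite instead
checks the package's set operations against an independent per-base
brute-force evaluator on thousands of randomized toy instances, so the
wrapper's semantics — not the dependency's reputation — carry the guarantee.

Distances follow gap semantics: 0 for any 1-bp overlap, otherwise the number
of bases strictly between the closest edges. One caveat is deliberate:
bookended intervals have distance 0 *without* overlapping, so "distance 0"
and "overlaps" coincide only up to that measure-zero case. Nearest-feature
ties break to the leftmost subject by (chromosome, start, end); determinism
here is a requirement of reproducible outputs, not a biological claim.

## Enhancer classification

The classifier is rule-based; it learns nothing from data. Its assumptions
are those of the underlying chromatin model: an enhancer is detectable as an
open-chromatin peak (ATAC or p300), its regulatory state is encoded by the
local histone marks, and peak callers' fold-enrichment and q/p columns are
comparable across libraries after thresholding.

Defaults, all inclusive comparisons (`≥` for folds, `≤` for significance):

| parameter | default | unit | rationale |
|---|---|---|---|
| narrow-mark filter (ATAC, p300) | fold ≥ 4, q ≤ 0.05 | — | macs2 narrow-mode convention plus an input-enrichment floor |
| broad-mark filter (H3K4me1, H3K27me3) | fold ≥ 2, q ≤ 0.1 | — | broad marks are flatter; a lower floor keeps true domains |
| H3K27ac filter | fold ≥ 5, q ≤ 0.1 | — | the activating mark gates class membership, so it is held to a stricter floor |
| broad-peak extension | 1000 | bp | histone peaks flank the nucleosome-depleted region the open-chromatin peak marks |
| TSS proximity filter | ±5000 | bp | separates enhancers from promoter chromatin |
| de novo extension | 2500 | bp | sparser cross-species data needs wider capture |
| de novo distal cutoff | >10 000 (strict) | bp | "distal" is stricter when no H3K4me1 evidence is available |

Order of operations for the in vitro classes: per-context intersection →
union across contexts → TSS filter → subtraction of the excluded mark →
merge. The per-context constraint is enforced *before* the union — marks are
never pooled across cell states prior to intersection, because co-occurrence
of marks in the same cell state is the biological signal. The TSS filter is
applied before the subtraction because that is the order in which the rules
are stated; the order is a `calling_params()` flag (`tss_filter_first`)
because for element-level subtraction the two orders commute anyway (both
steps only remove whole elements), making this a documentation choice rather
than a numerical one.

Subtraction of the excluded mark removes whole overlapping elements rather
than clipping bases (`subtract_element = TRUE`). Enhancers are counted as
units; base-level clipping would fragment elements into slivers that inflate
counts. The base-level variant is retained (and oracle-tested) behind the
flag.

Two asymmetries in the derived rules are intentional. The in vivo epiblast
rule filters histone marks by p-value (p ≤ 0.01) rather than q, reflecting
the lower power of in vivo ChIP; and it subtracts the in vitro H3K27ac union
in addition to the in vivo one, because absence of evidence of activity in a
noisy in vivo library is weak evidence of absence. The primed class consists
of H3K4me1 regions minus both other marks, so primed calls inherit the ±1 kb
extension of their defining broad peaks — their coordinates are mark-region
coordinates, not open-chromatin-peak coordinates like poised and active
calls; planted-recovery tests account for exactly this 1 kb pad.

Class redundancy resolves as: poised∩active and poised∩primed are removed
from both sets; active∩primed is attributed to active. PoiAct relabeling
intersects replicate H3K27ac sets before the overlap test, so a peak seen in
one replicate of two never activates a poised element.

## Conservation scoring

A chain file records ordered aligned blocks between a source and a
destination assembly. The package scores an interval by its **mapped
ratio** — aligned query bases divided by query length — under the single
best-scoring overlapping chain. No cross-chain stitching is performed: that
matches liftOver's default behavior and keeps target intervals contiguous.
The target interval is the bounding span of mapped bases (internal target
gaps are absorbed), strand-reflected for minus-strand chains; a configurable
expansion cap (10× query length) rejects pathological mappings as unmapped.

The conservation threshold (default 0.5, inclusive) is interpreted as
minimum mapped ratio — coverage, not sequence identity. A chain file does
not carry nucleotide-level identity, so "identity" thresholds in
chain-based pipelines are, operationally, coverage thresholds; only coverage
is implemented, and this is stated rather than guessed around. Threshold
sweeps are checked to be non-increasing on every run, which is a theorem
under this definition and therefore a cheap invariant against regressions.

## Association statistics

Promoter chromatin states are defined by TSS-window overlap with H3K4me3 and
H3K27me3 regions: both → bivalent, one → the corresponding single-marked
state, neither → unmarked. The window half-width defaults to 1 kb — roughly
the span of promoter-proximal nucleosomes — and is configurable because
external promoter-state annotations use varying windows. The four states
partition the gene universe by construction.

The Fisher test reports the sample (cross-product) odds ratio `(ad)/(bc)`
rather than the conditional-MLE estimate: it is a closed form, reproducible
without iterative fitting, and the difference is immaterial at the table
sizes involved; the two-sided p sums all hypergeometric table probabilities
at most the observed one (with a 1+1e−7 relative guard against floating-point
ties, the same guard `fisher.test` uses). Degenerate tables (a zero margin)
return a missing odds ratio and p = 1 with a warning rather than an error,
since they occur legitimately in small strata. The implementation is checked
against full fixed-margin enumeration on a 500-table grid.

Rank-sum comparisons use the exact distribution when the pooled sample is
≤ 25 without ties and the normal approximation with tie and continuity
corrections otherwise — `stats::wilcox.test` configured to exactly that
switch; fold changes are ratios of means by default (medians selectable),
with a missing value when the denominator mean is 0.

## Loop topology

Loop size is the distance between anchor midpoints. Anchor width is a
property of the loop caller's resolution, not of the loop, so midpoint
distance is the only size measure invariant to it. TAD membership is by
anchor midpoint for the same reason — an anchor straddling a boundary should
not belong to two TADs; loops with a midpoint in a TAD gap are `unassigned`
and excluded from the intra/inter fractions.

Partner annotation selects loops with at least one anchor (±10 kb) on a seed
element and labels the *other* anchor by the first matching category of an
ordered hierarchy, by default promoter (TSS ±7.5 kb) > other seed element >
PcG domain > other. The order is a declared configuration default — the
sensible priority when promoters are the regulatory endpoint of interest —
not a claim about any particular dataset. When both anchors sit on seeds the
loop contributes once per orientation, so category counts sum to the number
of seed-anchor contributions; a seed is never its own partner. Loop-set
overlap (both extended anchors must match the same candidate loop) is
directional by design: the matched fraction of set A in set B answers a
different question from its converse, and the two are reported separately.

## Contact matrices, balancing, pileups

Matrices are per-chromosome, symmetric, binned (5 kb default), stored
sparsely with entries canonicalized to the upper triangle. Coverage
normalization divides each entry by the product of its bins' relative
marginals; zero-coverage bins are masked and stay masked downstream.

KR balancing is implemented as symmetric iterative proportional fitting,
`x ← x / sqrt(rowSums(diag(x) A diag(x)))`, which has the same fixed point as
the Knight–Ruiz Newton scheme for symmetric non-negative matrices — weights
`x` with unit row sums of `diag(x)·A·diag(x)` — under a simpler convergence
contract: the iteration stops when the maximum absolute deviation of
covered-row sums from 1 falls below `tol` (default 1e−6), and raises an error
carrying the last residual at `max_iter` (3000). Closed-form cases
(`[[2,1],[1,2]] → x = 1/√3`; `diag(4,9) → x = (1/2, 1/3)`) and 200-matrix
random batteries pin the fixed point in the tests.

Pileups extract `(2w+1)²` snippets (w = half-width / resolution, half-width
250 kb by default per the window the field typically plots) centered on each
anchor pair, binned with ties to the lower bin, and divide them by a control
before averaging pixel-wise with missing pixels ignored. Two controls are
provided because "tool defaults" in this space are ambiguous: `expected`
divides by the matrix-wide per-diagonal mean at each pixel's separation;
`shifts` divides by the mean of `n_shifts` snippets displaced along the
diagonal by seeded uniform offsets in ±[w, 10w]. Neither is asserted to be
the one true control; on loop-free synthetic matrices they agree within the
tolerances the tests state. Pairs closer than the half-width to a chromosome
edge are skipped and counted, and a run with zero usable pairs is an error
rather than an empty result.

Loopiness is the single center pixel divided by the mean of the four corner
pixels (`corner_size = 1`, configurable to corner blocks); missing corner
pixels drop out of the mean, and an all-missing corner set yields a missing
value. The statistic is invariant to global rescaling of the window, which
is why it is comparable across normalizations.

## The synthetic-data generator

The generator's job is to make every downstream claim checkable by exact
planted recovery. It emulates: multi-context peak libraries whose planted
elements carry the mark signature of their class (with fold enrichments
drawn above thresholds and q-values below); CGIs placed within 3 kb of 75%
of poised elements (half of those overlapping, mirroring the strong exact
CGI overlap of poised versus active elements); one whole-chromosome chain
per chromosome with alignment gaps placed inside elements so each attains
its prescribed mapped ratio exactly; loops planted as PE–promoter
(bivalent-biased), PE–PE, PE–PcG and background pairs with p-values
straddling the significance filter; and Poisson contact matrices with
`(1+d)^−α` decay (α = 1) and planted center enrichments.

Placement rules make recovery unambiguous: planted elements stay >16 kb from
every TSS and ≥14 kb from each other (beyond any extension used by the
rules), noise sites stay ≥8 kb from planted elements, and each noise site
carries a mark signature no calling rule accepts (ATAC only, H3K27ac only,
H3K27me3 only, or H3K4me1 with a supra-threshold H3K27me3 companion — the
companion must clear its filter, otherwise a lone above-threshold H3K4me1
noise peak would legitimately call a spurious primed enhancer). Within those
constraints noise folds straddle their thresholds. PcG domains keep ≥22 kb
from TSS and ≥26 kb from elements so that an anchor placed on one can only
annotate as PcG.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: overlapping and nested peaks of the same mark,
context-specific (rather than shared) planted signatures, fragmented or
multi-chain alignments, trans contacts, anchor-width variation, replicate
biological variability, and any sequence-level signal. The planted-recovery
results certify the pipeline's logic, not the biology of any particular
dataset.

Determinism is a contract: each generator seeds its own stream from the
config seed with a fixed offset, and identical configurations produce
byte-identical files. The end-to-end check runs the whole pipeline twice and
compares every output file.

## Problem sizes and runtime posture

The shipped study conditions are a 2 × 10 Mb genome, 300 TSS, 200 planted
elements (60/60/50/30 across poised/active/primed/PoiAct), noise at 5
sites/Mb/mark, 100 loops, and a 500-bin contact matrix with 100 planted
pairs — sizes at which every oracle (per-base set algebra on ≤10 kb
chromosomes, literal rule evaluation on ≤100 kb toy genomes, per-base chain
walks, fixed-margin Fisher enumeration, 200-matrix balancing batteries) runs
comfortably on one CPU while still exercising each code path many times.

## Known limitations

* Interval strand is carried but ignored by all set algebra and proximity
  filters; nothing in the implemented rules is strand-aware.
* The chain mapper scores coverage, not sequence identity, and never
  stitches chains; elements split across chains under-score.
* `RunReport` deliberately excludes wall-clock timings (they go to stderr),
  trading a convenience for byte-identical reruns.
* The Fisher universes in published promoter-state enrichments are often not
  reconstructable from printed counts; the implementation is therefore
  validated against its own enumeration oracle, and users comparing against
  published odds ratios should first reconcile the gene universe.
* Balancing assumes the covered submatrix is effectively connected;
  disconnected components balance independently to unit row sums, which is
  correct but can surprise when comparing weights across components.
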