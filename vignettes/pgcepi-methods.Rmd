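---
title: "Methods: promoter chromatin states, demethylation escapees and X dosage in germline epigenomes"
author: "pgcepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter chromatin states, demethylation escapees and X dosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcepi)
```

## Scope and scientific setting

Human primordial germ cells (hPGCs) undergo a global erasure of DNA
methylation during fetal development, reaching a background of only a few
percent, while histone modifications take over much of the regulatory
work: promoter-enriched H3K4me3 tracks active transcription, sparse
H3K27me3 marks poised ("bivalent") promoters on lowly expressed genes,
and H3K9me3 with residual methylation guards repeat-rich regions that
resist demethylation. Two further phenomena hang off this landscape:
genomic regions that *escape* demethylation (hypermethylated islands in
the hypomethylated sea), and the dosage behaviour of the two active X
chromosomes in female germ cells, whose joint output rises well above the
male single-X level but stays below a full doubling.

`pgcepi` implements the downstream computations of such a study as a
reusable, fully tested pipeline: promoter chromatin-state classification
and stage dynamics, peak observed/expected enrichment, 5-kb-bin
demethylation-escapee calling, transposable-element (TE)
chromatin-preference scoring, and X-to-genome expression dosage
estimation. None of it requires controlled-access human data: a seeded
synthetic-epigenome generator plants every effect with known ground
truth, and the test suite verifies that each analysis recovers it.

## Promoter states and dynamics

A promoter is the symmetric window TSS ± 2000 bp (clipped at chromosome
ends; for a minus-strand gene the TSS is the annotation end − 1, the
standard convention). A promoter is *covered* by a mark when a called
peak overlaps the window by at least `min_overlap_bp` bases (default 1 bp
— the most permissive reading of "covered"; the threshold is exposed).
Coverage by both H3K4me3 and H3K27me3 anywhere in the window — not
necessarily the same base — makes the promoter bivalent; one mark gives
the single-mark states; neither gives `unmarked`. The four states
partition every promoter in every sample by construction.

Stage dynamics are pure bookkeeping over an identical promoter universe:
a 4×4 transition count matrix between consecutive stages whose marginals
must equal the adjacent stage totals (the alluvial mass balance, asserted
on every run), plus the source-state composition of promoters that are
bivalent now but were not at the previous stage ("gained bivalent").
Samples are staged by gestational week: 8–10 early, 11–15 middle, 20–23
late. Weeks 16–19 fall in a gap that no stage covers; they are labelled
`unassigned` and excluded from stage-stratified analyses rather than
force-assigned to a neighbour.

Expression tertiles split genes by rank (ascending) at ⌈n/3⌉ and ⌈2n/3⌉,
ties broken by a stable sort on gene id so the partition is
deterministic across runs.

## Genomic enrichment

For a peak set against a region set the package computes

$$R_{obs} = \frac{L_{peak\cap region}}{L_{peak}},\qquad
  R_{exp} = \frac{L_{region}}{L_{genome}},\qquad
  E = \frac{R_{obs}}{R_{exp}},$$

with all lengths measured on *merged* interval sets, so a base covered by
several peaks or several regions counts once and the statistic is
invariant to splitting a region into adjacent pieces. `E * R_exp ==
R_obs` holds as an algebraic identity and is asserted in the tests; a
fuzzed per-base membership-counting oracle confirms the interval
arithmetic to 1e-9.

## Demethylation escapees

The genome is tiled into non-overlapping 5-kb bins. Each bin's level per
sample is the unweighted mean of its CpG site levels (coverage weighting
is available behind a flag but is not the default — unweighted is the
simpler reproducible choice), and the *development average* is the mean
of the per-sample bin means across all PGC samples supplied, samples
equally weighted (not pooled CpGs; also switchable). The calling rules
are deliberately asymmetric, exactly as printed in the defining
thresholds:

* a **bin** is an escapee iff its development average is **strictly
  greater than 0.4**;
* a **TE subfamily** is an escapee iff its mean methylation (mean over
  copy-level CpG means) is **at least 0.35, inclusive**.

Both boundaries are covered by exact tests (0.40 → demethylated;
0.35 → escapee). A promoter inherits the call of the bin containing its
TSS — promoters are 4 kb against 5-kb bins, so the TSS rule is the
deterministic resolution of multi-bin promoters; promoters whose TSS bin
has no CpG are excluded with a warning. Escapee bins are further split
into repeat-rich/repeat-poor at ≥ 50% repeat-covered bases; this 0.5 is a
package parameter (the upstream literature derives its split from prior
real-data work, which is out of scope here).

## TE chromatin preference and positional effects

Each repeat copy gets mean H3K4me3 and H3K9me3 RPM over its span and the
pseudocounted ratio `(k4 + 0.01) / (k9 + 0.01)`: above 1.33 the copy is
H3K4me3-marked, below 0.66 H3K9me3-marked, otherwise ambiguous. The
0.01 RPM pseudocount guards zero-signal copies and is exposed; copies
shorter than 50 bp are excluded because a mean over so few bases is
unstable. Subfamily summaries report the three-way label proportions and
the majority label. Subfamilies are also ranked (ascending, 1 = lowest,
average ranks on ties) on methylation and on expression separately, and
scored by the rank sum, so a high score means jointly high methylation
and expression.

For positional effects, the genes within ± 10 kb of any copy of a
subfamily (gap measured between gene body and copy, overlap = 0;
boundary inclusive, so a gap of exactly 10 000 bp is "around") form the
around-set; all other genes are distal. The two sets partition the gene
universe, and the report compares promoter mark signal, expression and
methylation between them with a two-group test per quantity.

## X dosage

The dosage statistic is the fraction of summed expression on chrX,
`sum(FPKM[chrX]) / sum(FPKM)`, which is scale-invariant; the female/male
ratio of that fraction is the dosage factor (2.0 would be a full double
dose; values near 1.6 indicate dampening). The fraction-of-total form is
used because the phenomenon is reported as a proportion of total
expression; a per-gene median ratio is available as an alternative
method. Uncertainty comes from a percentile bootstrap over genes
(default 1000 resamples, seeded), resampling the same gene draw in both
sexes. Because genes are resampled with their planted mean
heterogeneity, the bootstrap interval is conservative for pure
noise replication — coverage of the planted factor runs at or above the
nominal level in the replicate studies.

Statistical comparisons throughout use a two-sample t test, Welch
(unequal variance) by default: group sizes and variances in these
comparisons are routinely unequal and no variance assumption is stated
for the original analyses; the classical pooled-variance Student test is
one flag away (`equal_var = TRUE`). When both groups are constant and
equal, `p = 1` by convention. No multiple-testing correction is applied
by default (tests are reported per panel); `p.adjust` can be applied to
batch reports by the caller.

## The synthetic epigenome

`sim_config()` defines the study conditions; `simulate_fixture()` emits
a complete file set (chrom-sizes, gene and repeat annotation, per-sample
peak BEDs and bedGraph tracks for three marks, per-CpG methylomes,
gene-FPKM and TE expression tables) plus truth tables under `truth/`
that the pipeline never reads. The defaults are:

* genome: two 5-Mb autosomes + a 3-Mb chrX; 2000 genes, ~10% on chrX,
  60% CGI promoters; samples: PGC at weeks {9, 14, 21} (female) and
  {9, 15, 23} (male) — one exemplar per stage — plus two week-9 somatic
  controls.
* methylation: one CpG per 100 bp; background mean 0.03 (a globally
  hypomethylated genome of a few percent); 2% of 5-kb bins planted as
  escapees with true level ~ Beta(14, 6) (mean 0.7), resampled above
  0.45 so that every planted escapee is identifiable in principle;
  per-CpG Beta noise at concentration 30.
* tracks: 100-bp bins, Gamma noise (shape 4, mean-preserving) around
  planted region means; H3K4me3 promoter amplitude increases with
  log1p(FPKM) (the expression coupling), H3K27me3 marks
  K27/bivalent promoters and escapee bins, H3K9me3 marks escapee bins
  and TE copies; female PGC samples add chrX-wide H3K27me3/H3K9me3 and
  chrX-CGI H3K4me3 elevation.
* TEs: SVA_A–F, LTR5_Hs, LTR14 and an L1 trio, 30 copies each, with
  planted H3K4me3:H3K9me3 ratios from {2.0, 0.5, 1.0} and graded
  methylation; LTR5_Hs additionally carries gene cassettes whose
  neighbouring genes get a 5× expression boost (the planted positional
  effect), while LTR14 cassettes are inert controls.
* expression: per-gene baseline ~ logN(1.5, 0.6); state-dependent means
  (bivalent ≈ 0.05 FPKM, H3K27me3-only 0.2, unmarked 0.5, active genes
  at baseline); sample noise is mean-preserving log-normal with
  sdlog 0.12 (~12% CV between biological samples). The spread and noise
  were fixed at these values because the planted X-dosage factor must be
  identifiable to ±0.05 from ~300 chrX genes — with a heavier
  between-gene tail the fraction-of-total estimator is dominated by a
  handful of genes and no noise level makes the recovery that precise;
  the chosen values are realistic for bulk expression sums and were not
  revisited afterwards.
* X dosage: the female chrX scale is solved analytically so the planted
  female/male ratio of X expression fractions equals the configured
  factor (default 1.6) exactly in expectation, which is what makes
  zero-noise recovery exact rather than approximate.

Layout discipline makes the planted truth exactly recoverable at zero
noise: genes sit on an even grid in the first 70% of each chromosome
with spacing chosen so that no peak can reach a neighbouring promoter;
escapee bins, TE copies and TE-proximal gene cassettes occupy disjoint
5-kb bins in the remaining territory behind a guard gap, so no planted
effect bleeds into another analysis. Peaks and tracks are generated
directly from the planted truth — read-level simulation and peak calling
are deliberately out of scope, since the package tests the downstream
logic, not an external caller.

What the generator does *not* emulate: real hg19 gene/repeat density and
clustering, overlapping genes, CpG islands as sequence features (CGI
status is a planted flag), replicate structure, mappability artefacts,
copy-number variation, or read-level noise. Passing tests therefore
demonstrate the correctness of the downstream computations under planted
truth, not the biological findings themselves; the original headline
numbers (escapee composition, bivalent counts, the measured 1.6-fold)
derive from controlled-access data and are not reproduction targets.

## Numerical and engineering choices

* Coordinates are BED-style 0-based half-open in every public container;
  1-based inputs (CpG positions) are converted at the reader. Interval
  arithmetic is delegated to IRanges/GenomicRanges behind this boundary.
* Region signal is the length-weighted mean of per-base track values;
  partial bins contribute proportionally, implemented with per-chromosome
  cumulative sums so region queries are O(1) each. A `sum` variant is a
  natural alternative; `mean` was chosen because profile figures are
  averages, and the choice only rescales comparisons.
* Track smoothing is a centred moving mean over bins with truncated
  windows at edges, never crossing chromosome boundaries (the "3-pixel"
  browser smoothing, with pixels read as track bins).
* Domain widths classify merged peaks (`max_gap` 0 by default: only
  overlapping or abutting peaks join) into `<1kb`, `1–2kb`
  (both bounds inclusive) and `>2kb`; the third class completes the
  partition.
* PCA ordination fixes each component's sign by making its
  largest-magnitude loading positive, so coordinates are reproducible
  across runs and platforms.
* Degenerate inputs are errors, not silences: empty region sets,
  zero-variance correlation inputs, promoter universes that differ
  between stages (reported with the symmetric difference), malformed
  file lines (reported with line numbers).

## Problem sizes in the test suite

The structural tests run on a 1-Mb toy genome and a 13-Mb default
fixture (2000 genes, 2600 bins, 330 TE copies, 8 samples × 3 marks).
The dosage replicate study uses 3 planted factors × 100 expression
redraws with 1000 bootstrap resamples each; null calibration of the
two-group test uses 1000 simulations. These sizes were chosen so the
whole suite exercises every planted effect in a few minutes on one CPU
while keeping all Monte-Carlo bands at ±2% or tighter.

## Known limitations

* Escapee calling assumes the 5-kb tiling of the calling rule; other bin
  widths work mechanically but the 0.4 threshold was defined at 5 kb.
* The dosage estimator assumes the two samples share a gene universe and
  that autosomal output is comparable between sexes; it does not model
  allele-specific expression or XIST/XACT locus effects.
* The pipeline consumes called peaks and normalized tracks; peak-calling
  parameters, alignment and multimapper assignment are upstream and out
  of scope.
* TE expression is consumed as a per-million table per subfamily; the
  multimapper-tolerant counting that produces it is not reimplemented.
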