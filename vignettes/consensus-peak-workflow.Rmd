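---
title: "Consensus peaks, QC and motif-expression integration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus peaks, QC and motif-expression integration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidypeaks)
```

This vignette is the package's account of the statistical procedures it
implements, the parameters that matter, the numerical decisions taken where a
procedure is under-specified, and what the synthetic-data generator does and
does not emulate.

## Coordinates and core types

All coordinates are 0-based, half-open, as in BED: an interval `[start, end)`
covers `end - start` base pairs. This matches the input formats (narrowPeak,
BED3) and makes width arithmetic exact — a 501 bp peak centred on summit `s`
is `[s - 250, s + 251)`. No function re-interprets coordinates; GRanges
objects used internally for overlap machinery are converted at a single
choke point. Peaks carry the upstream caller's −log10(p-value) as their
`score` (narrowPeak column 8, not the integer display score in column 5,
which is display-scaled and caps at 1000). Chromosome Y records are dropped
at parse time by default, since the genomic comparisons this workflow serves
exclude chrY; `drop_chrY = FALSE` disables this.

## Library QC

**Size classes.** Insert sizes are classified as sub-nucleosomal (< 147 bp,
the span protected by one nucleosome), mono-nucleosomal (180–247 bp) and
di-nucleosomal (315–473 bp). The gaps between these ranges (147–179, 248–314,
> 473 bp) form an explicit `other` class: the published class boundaries
leave them unassigned, but reported proportions must partition, so every
fragment belongs to exactly one class and proportions sum to 1.

**FROT and FRiP.** FROT is the fraction of fragments intersecting any
TSS ± 1 kb window by at least 1 bp. FRiP first labels peaks proximal
(overlapping a TSS ± 1 kb window) or distal, then assigns each fragment to
exactly one of `tss_peaks`, `distal_peaks`, `not_in_peaks`, checking proximal
peaks first so a fragment under both peak kinds counts as proximal — a
deterministic three-way partition. Fragments (sequenced pairs), never read
mates, are the counting unit throughout, so nothing is double-counted. The
1 bp intersection rule is used for all read-counting statistics; the stricter
40% rule (below) applies only to genomic-feature context, where it is the
stated convention. The TSS window interpretation ("within 1 kb of gene
annotation") is ambiguous between TSS ± 1 kb and gene body ± 1 kb; the
package implements TSS ± 1 kb and exposes `window` so the alternative radius
can be supplied.

**TSS profile.** Mean per-bp fragment coverage in TSS ± `window` (default
1 kb), averaged over TSS and binned at `bin` bp (default 10); minus-strand
windows are reversed so upstream is always left. Windows truncated by a
chromosome end contribute zeros rather than being dropped.

## The consensus workflow

`build_consensus()` chains the stages; each is exported separately.

**Fixed width (501 bp).** `extension = 250` bp per side; width is always
`2 * extension + 1`. Peaks whose window would cross a chromosome boundary
are *dropped*, not clipped — clipping would silently break the fixed-width
invariant the 50%-overlap arithmetic relies on. The dropped count is
reported.

**Iterative removal.** Overlapping peaks are resolved greedily: keep the
most significant remaining peak, discard everything overlapping it (≥ 1 bp),
repeat. Equal scores are broken by (chrom, start, sample id), smallest kept —
the procedure is published without a tie rule, and determinism is required
for reproducible output and for testing. The implementation resolves the
greedy recursion in one pass over a precomputed overlap graph; the test suite
checks it against a literal re-scanning oracle on 1,000 random instances and
verifies idempotence.

**SPM.** `spm_i = score_i / (Σ score / 1e6)`; the SPM vector of a sample sums
to 10⁶ exactly (unit relative tolerance 1e−9 in tests). A zero score-sum is a
validation error, not a silent NaN.

**Reproducibility filter.** After pooling and SPM-based iterative removal, a
survivor needs peaks with SPM ≥ `min_spm` (default 3) from ≥ `min_samples`
(default 2) distinct samples overlapping it by ≥ `min_overlap_frac` (default
0.5) of the fixed width — `ceiling(0.5 × 501) = 251` bp, which for
equal-width peaks is equivalent to reciprocal overlap. Three decisions here
were genuinely open:

- *Pooled-stage overlap is ≥ 1 bp, not 50%.* The published 50% threshold is
  attached to the reproducibility clause only; within-sample and pooled
  removal use plain intersection.
- *The supporting sample's own peak must meet `min_spm`;* the survivor's SPM
  alone is insufficient. This reads the filter as "SPM ≥ 3 observed in ≥ 2
  samples", a condition on samples. Because the survivor holds the maximal
  SPM among its overlaps, any retained peak automatically satisfies
  SPM ≥ `min_spm` itself.
- *One sample may support several distinct survivors;* each survivor is
  evaluated independently. Restricting support to one survivor per sample
  would make the result depend on survivor ordering.

**Cross-set merge.** Each input consensus set's SPM vector is re-normalized
to sum to 10⁶ so a deeper or cleaner group cannot dominate, sets are pooled,
and iterative removal is rerun. Every survivor records which input sets
contributed a peak overlapping it by ≥ 50% of the fixed width;
`classify_peaks()` turns this provenance into shared / set-specific labels
and a percentage accounting of the merged set.

## Comparison utilities

**Feature context (40% rule).** An interval is assigned a feature when at
least 40% of *its own length* falls within a single feature record; among
qualifying labels the precedence promoter > 5′UTR > 3′UTR > exon > intron
applies, and intervals qualifying nowhere are distal. Promoter-first matches
the promoter definition (TSS ± 1 kb) taking priority in feature accounting;
the remaining order runs from most specific transcript annotation to least.
The interval's own length as denominator is the read-centric published
convention; peaks reuse the same code path.

**Shape metrics.** Per-bp coverage within one peak window gives
`summit_height` (maximum) and `base_width` (the length of the maximal
contiguous run containing the coverage argmax with coverage ≥ half the
maximum). The contiguous-run definition, rather than total bp above
half-maximum, is robust to multimodal noise in the window. Ties in the
argmax take the leftmost position.

**Sample distances.** Euclidean distances over per-sample count vectors
(optionally log2(x+1)-scaled, default raw), returned as a symmetric matrix
with zero diagonal.

**Differential ranking.** `differential_rank()` is a deliberately
non-statistical stand-in: per-peak `log2((mean CPM_a + 1)/(mean CPM_b + 1))`.
It produces no p-values and models no dispersion; it exists so the
integration stage is drivable end to end. A proper differential
accessibility analysis should use a count model (e.g. DESeq2), which is out
of scope here.

## Motif-expression integration

Expression is transformed per sample as `log2(CPM + 1)`; the pseudocount 1
keeps zero counts at exactly 0 and makes the "robustly expressed > 2 log2CPM"
threshold meaningful near zero. Condition-level expression is the arithmetic
mean of replicate log2CPM values (transform first, then average — not the log
of mean CPM). Motifs are collapsed to one record per TF gene, keeping the
lowest-FDR motif (this per-TF collapsing is one reading of "non-redundant";
motif-cluster collapsing is another, and would need a cluster annotation the
inputs do not carry). The top `top_k` motifs by enrichment (default 25; 40 is
conventional for footprinting-tool outputs) are filtered to TFs with target
expression strictly above `expr_min = 2` log2CPM and re-ranked by
`expr_target − expr_background`, descending; ties break by enrichment FDR and
then gene symbol. The first `n_top_report = 5` are the nominated candidate
master TFs. The motif → TF gene mapping is a required input column rather
than being parsed out of motif names, which differ across motif databases
and tools.

## The synthetic-data generator

`simulate_experiment()` emulates a two-state (default `esc` vs `mef`),
two-platform, three-replicate accessibility study at desk scale. Defaults,
chosen once:

- **Genome**: 2 chromosomes × 5 Mb. Large enough for ~100k scoring windows
  per sample, small enough that the full pipeline runs in seconds.
- **Planted regions**: 400 non-overlapping 400 bp regions on a 2.5 kb grid,
  ≥ 2 kb from chromosome ends; 60% accessible in both states, the rest split
  between state-specific sets. Each region carries a lognormal intensity
  (log-sd 0.5): real peak landscapes have a continuum of strengths, and it is
  the weak tail sitting near the reproducibility threshold that produces
  set-specific peaks with systematically lower SPM — without intensity
  heterogeneity no set-specific peaks would exist at all.
- **Depth**: 50,000 fragments per sample, with `frip_target = 0.6` of them
  drawn from planted regions (centre Gaussian around the region centre,
  sd = width/4), matching the signal-to-background quality reported for
  OMNI-ATAC libraries (more than half of reads in peaks).
- **Insert sizes**: per-platform mixtures over the four size classes.
  The Illumina-like mixture is (sub .45, mono .33, di .13, other .09) and the
  BGI-like mixture (sub .585, mono .315, di .05, other .05) — a 1.3× sub
  ratio and 2.6× di ratio, the reported direction and magnitude of the
  platform bias. Within-class length distributions are invented (the classes
  are only defined by their boundaries): uniform on 30–146 for sub,
  discretized Gaussians (200, 20) and (400, 30) truncated to the mono/di
  ranges, uniform over the gap ranges for other.
- **Peak calls**: a windowed Poisson scorer stands in for the out-of-scope
  upstream caller: 501 bp windows stepped by 100 bp, fragment-midpoint count
  `k` scored as `−log10 P(X ≥ k)`, `X ~ Poisson(background_rate × 501)`,
  candidates above score 2 (p < 0.01, the conventional loose calling
  threshold), summit at the window coverage maximum. It is deliberately
  simple so scores have an analytic oracle. Low-score noise peaks (score
  uniform on (2, 4]) are injected at 2 per Mb. Adjacent windows overlap by
  construction, so iterative removal is always exercised.
- **Expression**: negative-binomial counts (dispersion 0.1) over 5 planted
  master TFs (mean 500 target / 1 background), 10 decoy TFs (half at mean 2
  in both states — below the robust-expression threshold — and half flat at
  50), and 200 background genes with lognormal means around 5,000, which
  puts library sizes near 10⁶ so counts are on a realistic CPM scale. The
  motif table lists master motifs with the smallest FDRs, decoys after, and
  redundant second motifs for two masters to exercise deduplication.

All randomness flows from one root seed through namespaced per-stage,
per-sample sub-seeds, so any sample is regenerable independently and
byte-identically.

**What the generator does not emulate** — and hence what passing tests do not
show about real data: sequence content (no Tn5 insertion-site or GC bias, no
FASTQ), duplicate reads, mitochondrial contamination, mappability structure,
correlated region-to-region intensities, chromatin-state-dependent fragment
length (real promoters are depleted of nucleosomal fragments; here length and
location are independent), and realistic motif co-occurrence. Tests on this
generator validate the *algorithmic* contracts of the pipeline, not
biological recovery rates on real libraries.

## Problem sizes and runtime of the test suite

The statistical tests run at the generator's default scale: mixture recovery
at n = 50,000 fragments (3 binomial SEs), consensus recovery across 10 seeds
(three replicates each), the shared-versus-specific SPM contrast and
condition clustering on full 12-sample experiments, the sub-nucleosomal
sweep at four mixture weights, and master-TF recovery across 100 seeds. The
full suite completes in about two minutes on one CPU; `scripts/acceptance.R`
in about one.

## Known limitations

- `replicate_consensus()` assumes fixed-width, internally non-overlapping,
  SPM-normalized inputs; `build_consensus()` is the safe entry point.
- The 50%-overlap threshold is computed from the configured fixed width; peak
  sets of heterogeneous widths would need a reciprocal-overlap variant.
- `differential_rank()` is plumbing, not inference (see above).
- Support counting treats samples symmetrically; there is no
  irreproducibility-rate (IDR) style modelling of rank consistency.
- The feature annotator assigns one label per interval; overlapping gene
  models resolve by the fixed precedence rather than by transcript isoform.
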