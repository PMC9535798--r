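---
title: "Methods: binding-by-response classification of protein-coding genes"
author: "crossreg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-by-response classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossreg)
```

# The analysis

crossreg implements an integrative ChIP-seq x RNA-seq analysis for studies
of transcriptional repressors such as the Drosophila MBT-domain protein
L(3)mbt and its partner Lint-O in ovarian somatic cells. The question the
analysis answers is *where does the factor sit on each gene, and what
happens to that gene's expression when the factor is depleted?* Every
protein-coding gene in a fixed universe receives:

* a **binding class** from the factor's ChIP peaks —
  `promoter` (a peak overlaps a window from 0.35 kb upstream to 0.1 kb
  downstream of a transcript TSS), `nonpromoter_genic` (a peak overlaps the
  gene span but no promoter window), or `unbound`;
* an **expression class** from an RNAi knockdown versus control contrast —
  `up`, `down`, or `unchanged` at FDR < 0.01.

The cross of the two classifications is a 3x3 **regulation table**; the
"genes under the control of the factor" are those bound anywhere and
upregulated upon depletion (derepression, the signature of a repressor).
Two factors' regulated sets are compared as a Venn partition, with optional
hypergeometric enrichment of the shared set.

# Stage-by-stage model and parameter choices

## Promoter windows

The promoter of a TSS at position $t$ spans $[t - 350,\; t + 99]$ on the +
strand (mirrored on the − strand): 350 bp upstream through 100 bp
downstream, where "downstream" includes the TSS base, for exactly
450 bp. This window derives from the reported DNA-binding footprint of
L(3)mbt around fly promoters; both distances are arguments of
`promoter_windows()`. A gene's promoter is the **union of windows over all
of its distinct transcript TSSs** — the annotation is transcript-level and
no canonical TSS is singled out, so the most permissive per-gene reading is
used; a canonical-TSS variant can be had by subsetting the transcript table
first. Windows are clipped at chromosome boundaries.

## Peak reconciliation

ChIP replicates arrive as MACS2 narrowPeak files. Two steps precede
annotation:

1. **q-value filter** (`filter_peaks_by_q()`): peaks with
   $-\log_{10}(q) > 100$ are dropped (strict inequality; threshold
   configurable). Such hyper-significant peaks are characteristic of
   collapsed repeats and artifact regions. The originating description of
   this filter is sign-ambiguous ("log10-converted q-value over −100");
   read literally the other way it would discard all but the most
   significant peaks, i.e. nearly everything, so the artifact-removal
   reading is implemented and documented rather than asserted.
2. **Common peaks** (`common_peaks()`): replicate reconciliation keeps
   *common, not merged* peaks — every overlapping rep1 x rep2 pair
   contributes the **intersection** of the two intervals, scored with the
   pair's minimum $-\log_{10}(q)$ (the weaker evidence). One rep1 peak
   overlapping two rep2 peaks therefore yields two common peaks, and the
   output never extends beyond either input. Abutting intervals share no
   base and do not count.

Intersection geometry doubles as a noise filter: spurious peaks rarely
reproduce across independent replicates, which is why the synthetic-data
recovery stays at ~100% even with planted noise (below).

## Binding classification

`assign_binding_class()` applies strict precedence: promoter overlap beats
genic overlap beats nothing, and adding peaks can never demote a gene.
"Genic" means the full gene span, introns included — intronic binding is a
documented mode for these factors (e.g. at *ago3*). Peaks are strandless;
the promoter's orientation comes from the gene. A peak may support several
genes at once (a promoter peak of one gene can sit in a neighbour's
intron). Peaks on chromosomes absent from the annotation are ignored with
a warning rather than an error, since scaffold mismatches are routine.

## Differential expression

The spec of this stage in the original studies is simply "DESeq2 at
FDR < 0.01"; crossreg implements a documented, self-contained
simplification with the same skeleton:

* **Normalisation**: median-of-ratios size factors (`size_factors()`),
  falling back to library-size scaling when no gene is expressed in every
  sample.
* **Dispersion**: per gene, method-of-moments on normalised counts within
  each condition, $\hat\alpha = \max(\alpha_0, (s^2 - \bar x)/\bar x^2)$
  with floor $\alpha_0 = 10^{-8}$, pooled across conditions by
  normalised-count-weighted average (`estimate_dispersion()`). In
  `de_test()` the per-gene values are additionally floored at the
  across-gene **median of informative estimates**. This is the dispersion
  sharing idea in miniature: with three replicates the per-gene variance
  estimate has ~4 degrees of freedom, and plugging it into a normal-
  reference Wald statistic is anticonservative in exactly the genes where
  the variance is underestimated; a genome-wide floor removes that tail
  while leaving genuinely high-dispersion genes their own estimate.
  `moderate_dispersion = FALSE` restores the pure per-gene behaviour.
* **Test**: $\log_2 \mathrm{FC} = \log_2\frac{\bar x_B + c}{\bar x_A + c}$
  with pseudocount $c = 0.5$ (so zero-count genes stay finite), standard
  error by propagating the NB variance $\mu + \alpha\mu^2$ of each group
  mean through the log-ratio, two-sided normal p, Benjamini–Hochberg q.
  Genes with all-zero counts are flagged and excluded from testing.
* **Classification**: `up` iff $q <$ 0.01 and positive fold change;
  `down` iff $q <$ 0.01 and negative; all else `unchanged`. No extra
  fold-change cutoff is imposed, since none is part of the original rule.

Calibration and power are properties of the shipped tests: across ten
5,000-gene null simulations (3 vs 3, $\alpha = 0.05$) the fraction of
genes at $q < 0.01$ stays at zero, and planted 4-fold effects at mean 200
are recovered with power > 0.95. The power simulation embeds its 500
planted genes in a 2,000-gene null background: median-of-ratios
normalisation assumes most genes are unchanged, and a simulation in which
*every* gene moves four-fold is indistinguishable from a library-size
difference — no normalisation-based method can (or should) detect it.

This stage intentionally does not reproduce DESeq2 numerically: no
trend-fitted dispersion prior, no LFC shrinkage, no Cook's filtering, no
independent filtering. On real data the gene lists will differ in the
tails; all downstream bookkeeping is agnostic to which DE engine produced
the `up/down/unchanged` labels, and `cross_classify()` accepts any table
with `gene_id` and `expr_class`.

## Integration arithmetic

`cross_classify()` partitions the universe completely: every universe gene
must carry a binding call, and genes missing from the DE output (all-zero,
hence untestable) are classed `unchanged` with a message so totals always
add up. Printed percentages use `percent_of_group()`: one decimal, halves
rounded **away from zero** — the only convention consistent with all
fourteen published (count, group, %) triples this package re-derives
(e.g. 1044/7460 = 13.995 → 14.0). Enrichment (`hypergeometric_enrichment()`)
is an upper-tail hypergeometric test against the **classification
universe**, not the whole annotation, because the study's gene space is
the fixed protein-coding universe. Brain-lobe volumes use the prolate
spheroid formula $V = \tfrac{4}{3}\pi a b^2$ with $a$ the major and $b$
the minor semiaxis as measured under a stereo microscope.

## Scale-regions metaprofiles

`scale_regions_matrix()` reimplements the deeptools-style scale-regions
computation: 3 kb fixed flanks binned at 50 bp, the gene body resampled to
a constant 5 kb (100 bins). Body bins average an **equal fraction** of the
gene length with partial bases weighted fractionally, which avoids
aliasing on genes shorter than the bin count and makes the body mean of a
row exactly the per-base mean of the gene body (an invariant the tests
assert at 1e-9). Minus-strand rows are orientation-flipped so column 1 is
always 5'-most; since the bin widths are symmetric about the body, flipping
a gene's strand exactly column-reverses its row. The 50 bp bin width and
100 body bins are the deeptools-like defaults; the originating analysis
does not state its bin size, so metaprofile agreement with published
heatmaps is qualitative by construction. Rows are ordered by descending
mean (the heatmap convention) with gene ids retained.

## Co-IP candidate funnel

`select_candidates()` encodes the quantitative filter applied after
label-free quantification of a bait co-IP against a bait-depleted
control: keep proteins with abundance ratio control/KD **strictly greater
than 4** and PSM **strictly greater than 1** (i.e. at least two
peptide-spectrum matches), then drop ribosomal proteins and the bait.
A protein detected only when the bait is present (KD abundance zero,
control positive) passes as an infinite ratio — detection contingent on
the bait is the strongest evidence, not a missing value; `zero_kd =
"skip"` gives the conservative alternative. Records absent from both
channels are skipped with a warning. Ratios are protein-level; the
peptide-versus-protein aggregation level is not stated in the originating
description, and protein-level is the common Proteome Discoverer export.
`categorize_candidates()` then tags candidates whose annotation intersects
a target set (e.g. DNA binding / chromatin regulation), reporting
unannotated candidates rather than dropping them silently.

# The synthetic study

`simulate_study()` generates, from one seed, the structure of the
deposited data at desk scale: a 2,000-gene annotation on four 5.5 Mb
chromosomes (lengths log-uniform 1–20 kb, ≥1 kb intergenic gaps, 1–3
transcripts with ≤200 bp TSS jitter); for each of two factors, duplicate
narrowPeak files and a coverage bedGraph; a 9-sample count matrix
(triplicate control plus triplicate knockdown per factor, sharing one
control set, as in the emulated design); and a 100-protein quantification
table.

Defaults are the emulated study's conditions and are not tuning knobs:

| parameter | default | where it comes from |
|---|---|---|
| promoter / genic binding fractions | 0.535 / 0.076 | the published per-class rates among 13,951 genes |
| up / down fractions among bound genes | 0.16 / 0.14 | the published response rates among promoter-bound genes |
| effect size | log2FC ±2 | derepression in these studies is strong (several-fold); magnitude configurable |
| NB dispersion | 0.05 | typical well-replicated cell-culture RNA-seq |
| replicates | 2 ChIP, 3 RNA-seq | the emulated design |
| replicate jitter | ≤20 bp | peak-call coordinate wobble between replicates |
| noise peaks | 5 per Mb per replicate, independent | exercised so that common-peak intersection is seen to remove them |
| funnel strata | 79 background + 21 passing, 4 flagged, 7 annotated | the published 100 → 21 → 17 → 7 funnel |

Planted truth (classes, fold changes, interactors) is returned in memory
and written as `truth.json`, so every stage is checkable end to end:
binding recovery is 100% in the noise-free regime and ≥99% at default
noise; the pipeline's 3x3 table matches the planted contingency within
binomial sampling noise with ≥95% sensitivity for the bound-and-up set.

What the generator deliberately does **not** emulate: read-level data
(peaks and counts are drawn directly, so aligner/caller idiosyncrasies are
out of scope); correlated binding between the two factors (classes are
planted independently, so the synthetic two-factor Venn shares only the
random-expectation overlap, unlike the strongly co-bound factor pairs in
the real studies — the overlap *arithmetic* is what is being tested, not
the biology); GC/mappability bias; and trans effects of one factor's
depletion on the other's targets. Passing recovery tests therefore
validates the pipeline's bookkeeping and statistics, not any claim about
real chromatin.

# Numerical and degenerate-input choices

* Coordinates are 1-based closed (`GenomicRanges`) in memory; GTF is
  native, BED-family formats convert at the I/O boundary via rtracklayer.
  Writers emit plain `sprintf` lines so identical inputs give
  byte-identical files (the determinism the tests assert).
* Ties: nearest-TSS ties break by smaller distance, then lexicographic
  gene id, then transcript id; candidate ordering by descending Sum Pep
  Score, ties by protein id; BH is stable under ties by construction.
* Degenerate inputs: empty peak files give empty peak sets; an empty
  annotation is a valid (empty) GTF; zero-variance vectors make the
  replicate correlation NA with a warning; zero library sizes, all-zero
  samples, overlapping bedGraph intervals and malformed narrowPeak lines
  are errors, not silent repairs.
* `run_study()` validates every referenced path before computing anything,
  logs every threshold to stderr, and writes a `summary.json` whose
  percentages are recomputed from its own counts (an internal-consistency
  invariant the tests check).

# Problem sizes

The shipped test-suite and acceptance computations use the generator at
its default scale: 2,000 genes for classification recovery and the
end-to-end pipeline, 5,000 genes x 10 seeds for null calibration, 2,500
genes for power, 100 proteins for the funnel, with smaller hand-built
fixtures for the exact-arithmetic and oracle-equivalence checks. These
sizes were chosen so the complete suite runs in about a minute and a half
on a laptop while keeping every binomial tolerance meaningful.

# Known limitations

* The DE stage is a simplification; genome-wide DE counts from real data
  will not numerically match a DESeq2 run (see above).
* The 13,951-gene universe of the emulated study is reconstructible only
  from the matching annotation release plus its exact filter, which is not
  public; on real data, supply the universe explicitly.
* TSS-distance bin edges for the distance-based classification are a
  required input; none are canonical.
* bigWig is not read; convert coverage to bedGraph first.
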