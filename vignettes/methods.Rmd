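---
title: "Methods: quantifying Polycomb domain remodeling with germchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Polycomb domain remodeling with germchrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germchrom)
```

germchrom quantifies the transition between two H3K27me3 states of germline
chromatin: a broad, non-canonical distribution over all inactive sequence
(the progenitor "ground state") and the canonical pattern of focused
enrichment on Polycomb (PcG) domains that appears during nurse-cell
differentiation. This vignette documents the models and estimators, the
parameters that matter, the synthetic-data generator used for validation,
and the numerical and design choices behind both.

## Genome segmentation and binning

The unit of chromatin annotation is a **four-class segmentation**:
`active`, `PcG`, `Hp1`, `inactive`. When the input is a nine-state model,
`simplify_states()` maps states 1–5 to active, 6 to PcG, 7–8 to Hp1, and 9
to inactive, merging touching same-class neighbours. All coordinates are
0-based half-open (BED convention), so a domain printed as
`ARM:START..END` has span `END − START`; `domain_span_kb()` implements
exactly this convention, which reproduces printed domain lengths (e.g.
`2L:2198000..2209000` is 11 kb).

ChIP signal is summarized in **overlapping bins**: width 5000 b, step
500 b (`make_bins()`), so each genomic position is covered by up to ten
bins and a bin count on an unmasked chromosome of length `L >= width` is
`floor((L − width)/step) + 1`. Bins are dropped when they extend past a
chromosome end, lie on an excluded chromosome, or overlap a masked
interval. Two deliberate choices here:

* **Partial mask overlap drops the bin entirely.** Exclusion regions
  (pericentric heterochromatin, amplified loci) have fuzzy edges; keeping
  partially masked bins would mix signal regimes inside one bin, so the
  conservative rule is applied. Masks are ordinary interval tibbles the
  user can edit.
* **A bin gets a class only under full single-class coverage**
  (`assign_bin_class()`). A bin overlapping two classes or uncovered
  sequence is `mixed` and excluded from every class-stratified summary.
  The alternative — requiring only the absence of a second class — would
  admit bins over assembly gaps; full coverage is stricter and makes the
  per-base oracle in the tests exact. The cost is that domain edges are
  slightly underrepresented.

PcG bins additionally carry a **PRE flag** (`flag_pre_bins()`): a bin is
flagged when at least one summit from a composite peak-summit list falls
in `[start, end)`. The composite list is a concatenation deduplicated by
exact position; no merging radius is applied because none is defined —
two summits 1 b apart simply both flag the same bins.

Genes are reduced to the **largest region shared by all isoforms**
(`collapse_isoforms()`, the intersection of isoform spans) and classified
with precedence **PcG > active > inactive** on any-overlap
(`classify_genes()`): touching a PcG domain by one base makes a PcG gene.
Genes whose isoforms share no sequence collapse to an empty interval; they
are excluded by default (classification of an empty interval is an error),
since no principled class exists for them.

## Spike-in normalized enrichment

Libraries carry a per-read `species` tag (`target` or `spike`), standing
for the two genomes of a hybrid alignment. For an IP/Input pair the
normalization factor is

```
alpha = (spike_Input / total_Input) / (spike_IP / total_IP)
```

applied to the IP track (`spike_normalization_factor()`). The direction
matters: the spike-in chromatin mass is constant per sample, so a
genome-wide *gain* of target methylation dilutes the IP spike fraction and
*raises* alpha, scaling the IP signal up — which is what makes total
signal comparable across cell types. Per-bin enrichment is

```
E_b = (alpha * RPM_IP_b + eps) / (RPM_Input_b + eps)
```

Reads are assigned to bins **by midpoint**: with overlapping bins a read
contributes to every bin containing its midpoint (one per lattice offset).
Midpoint assignment avoids the double-counting ambiguity of overlap-based
assignment at bin edges and is standard for binned ChIP summaries. The
pseudocount `eps` defaults to the RPM equivalent of one read in the
smaller library: small enough not to perturb typically covered bins, large
enough to bound log-ratios on empty ones. With `alpha = 1` and `eps = 0`,
the Input-RPM-weighted mean of `E` over a common bin universe is exactly 1
(a conservation identity the tests check).

Class-stratified views (`class_density()`) are kernel densities of
`log2 E` computed *within* each class, so every curve integrates to 1 and
classes of very different size are comparable as proportions. Smoothing is
Gaussian with Silverman's rule-of-thumb bandwidth (the `stats::density()`
default), configurable.

**Domain calls** (`call_domains()`): a domain at least 10 kb long is
enriched when the mean `E` over class-matching, non-mixed bins fully
inside it reaches a threshold, default 2.0. The threshold is a package
choice — "highly enriched" has no canonical numeric value and published
domain lists involve manual curation — so it is an explicit argument, and
sharing counts on real data should be read as threshold-dependent. Domains
containing no usable bin yield `NA` rather than a silent drop.
`share_domains()` reduces a domain-by-sample boolean matrix to counts
enriched in all/some samples and the percentage shared,
`100 * |all| / |any|`.

**Fold changes between samples** (`fold_change_summary()`) are per-bin
`log2(E_A/E_B)` with per-class medians, quartiles, and the conventional
notch half-width `1.58 * IQR / sqrt(n)` as an approximate 95% CI of the
median. When bins carry a PRE flag, PcG bins are split into PRE-containing
and PRE-lacking summary classes.

## Expression fold-change trajectories

`tpm()` is the standard length-normalized within-sample unit (columns sum
to 10^6). `size_factors()` is the median-of-ratios estimator: the per-gene
reference is the geometric mean across samples over genes with no zero
count, and a sample's factor is the median ratio to that reference. It
matches the reference implementation in the DESeq2 package to numerical
precision (checked in the tests), but dispersion shrinkage and Wald
testing are deliberately *not* reimplemented: the quantities of interest
here are distributional medians, not per-gene significance calls.

`gene_fold_change()` reports
`log2((mean normalized A + prior) / (mean normalized B + prior))` with
`prior = 0.5` normalized counts, bounding fold changes of zero-count genes.

The headline statistic is the **relative median trajectory**
(`relative_median_trajectory()`): per stage (each compared to the same
undifferentiated baseline) and class, the median fold change across genes
divided by the active-class median at that stage. The active class is
pinned at exactly 1 by construction, so repression of inactive/PcG genes
reads directly as a relative deficit. Confidence intervals are percentile
bootstrap over genes (default 1000 resamples, seeded; class and active
genes resampled independently); classes with fewer than 10 genes are
flagged unreliable. The bootstrap construction is a package choice — a 95%
interval is standard for such plots but its construction is rarely stated —
and its coverage is verified by simulation in the test suite (200
replicates at a true relative median of 0.7).

A known property worth stating plainly: when a large fraction of genes
shifts in one direction (e.g. a quarter of all genes up 1.4-fold),
median-of-ratios factors absorb part of the shift, biasing *raw* class
medians by several percent. The relative median cancels this exactly,
which is why the recovery checks and the acceptance script use it; raw
medians are still tested, at the looser tolerance their bias implies.

## Reporter induction and genotype contrasts

For each (line, stage, genotype) cell, the baseline is the pooled mean of
all non-heat-shocked replicates, and each heat-shocked replicate's
induction is `I_r = intensity_r − baseline` (`induction()`). Replicates
are ovary pairs: cells measured within one ovary are averaged upstream, so
the test unit matches the experimental unit and pseudo-replication is
avoided. Induction is invariant to additive intensity offsets and
equivariant to rescaling.

`genotype_contrast()` runs the unpaired, two-tailed, pooled-variance
Student's t-test on induction replicates, with tiers `**` (p < 0.01), `*`
(p < 0.05), `N.S.`. No multiplicity correction is applied by default —
matching the raw-threshold convention of such panels — but
`bh_correct = TRUE` applies Benjamini–Hochberg across the tested cells.

One calibration caveat is documented rather than hidden: the pooled t
treats the subtracted baseline as a known constant. When baseline
replication is comparable to induction replication, baseline sampling
noise inflates the true variance of the group means beyond what the
within-group spread estimates (by up to sqrt(2) on the t scale at equal
arms), making the test anticonservative. The null-uniformity check in the
test suite therefore runs in the well-estimated-baseline regime (200
baseline replicates), where the statistic is calibrated; with few baseline
replicates, tier thresholds should be read as approximate.

## The synthetic-data generator

The generator replaces FACS-sorted, sequenced inputs with seeded draws
whose statistical structure matches the real data flow:

* **Genome**: chromatin segments with geometric (memoryless) lengths,
  default mean 20 kb — the scale of published PcG domains (5–120 kb,
  most a few tens of kb) — and class weights
  active 0.45 / inactive 0.35 / PcG 0.10 / Hp1 0.10, a euchromatin-rich
  mix with PcG domains as a small minority. Adjacent segments always
  differ in class. Genes (default 500 per class, 0.5–3 kb) are placed
  wholly inside segments of their class, with 1–3 isoforms whose
  intersection is the collapsed gene.
* **ChIP**: Input target reads uniform; IP target reads with per-base rate
  proportional to the class multiplier, defaults
  active 0.2 / inactive 2 / PcG 10 / Hp1 2 — the canonical differentiated
  pattern with a 5-fold PcG-over-inactive ratio and strong depletion on
  active chromatin. Reads are 75 b (standard short single-end). Spike
  reads live on a dedicated spike chromosome; the Input spike fraction
  defaults to 0.01, the realistic order for a few thousand spiked cells
  against half a million target nuclei. The IP spike fraction is *derived*
  — spike mass fixed, target mass scaled by the length-weighted mean
  multiplier — so global methylation changes move the spike fraction,
  which is precisely the signal alpha exploits.
* **Expression**: negative-binomial counts (default dispersion 0.05, a
  typical bulk RNA-seq value) around log-normal per-gene means (median
  200), with condition-B means multiplied by `2^class_log2fc`.
* **Reporter**: Normal fluorescence noise (default sd 5 a.u. around a
  background of 50), heat shock adding `base_induction * silencing_factor`
  (defaults 100 and 1), truncated at zero.

All randomness descends from one integer seed; each stage hashes its name
into a child seed (`child_seed()`), so adding a stage never perturbs the
others, and identical configs give byte-identical outputs (the pipeline
manifest records md5 digests to prove it).

What the generator does **not** emulate: sequence content and alignment
artifacts (no FASTQ, no mappability structure), PCR duplicates,
fragment-length variation, cross-mapping between target and spike genomes,
copy-number differences between polyploid stages, and cell-type impurity
from sorting. Passing recovery tests therefore demonstrates that the
estimators are correct and calibrated for data with this statistical
structure, not that real libraries are free of these artifacts.

## Problem sizes and runtime choices

The validation suite uses deliberately modest sizes chosen so the full
suite runs in about a minute while keeping sampling error well inside the
asserted tolerances: 2 chromosomes of 1 Mb (≈4000 bins) with 5 × 10^5
reads per library for multiplier recovery (10% tolerance; observed error
is ~1%), 2000 genes per class for fold-change recovery (5% on the relative
median), 50–200 ovary-pair replicates for reporter recovery, 300–500
simulations for calibration checks, and a 0.3 Mb single-chromosome
configuration for the end-to-end determinism check. The acceptance script
uses the same sizes.

## Known limitations

* Domain sharing on real data depends on the enrichment threshold; there
  is no attempt to reproduce manually curated domain boundaries.
* The fold-change pipeline reports distribution-level statistics only; it
  is not a differential-expression tool and computes no per-gene p-values.
* Interval work loads everything in memory; the package targets
  desk-scale analyses (toy genomes, binned summaries), not whole-genome
  read-level processing of deep libraries.
* Hp1 chromatin is carried through segmentation and binning, but no
  Hp1-specific analyses are provided.
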