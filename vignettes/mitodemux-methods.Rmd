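---
title: "Demultiplexing pooled single-cell libraries with mitochondrial germline variants"
author: "mitodemux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demultiplexing pooled single-cell libraries with mitochondrial germline variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodemux)
```

## The problem

Pooling cells from several donors into one single-cell library cuts cost,
removes batch effects between samples and turns many doublets into
detectable events — provided each barcode can be traced back to its donor.
Tools that genotype cells from nuclear variants need reasonable coverage of
the nuclear genome, which chromatin assays (scATAC-seq and its mitochondria-
retaining variants, ASAP-seq, DOGMA-seq) do not provide per cell.  The
mitochondrial genome is the exception: hundreds of copies per cell, 16,569
bp, and a private set of inherited homoplasmic substitutions per maternal
lineage.  Those germline variants act as an endogenous barcode.  `mitodemux`
reconstructs donor-of-origin and flags cross-genotype doublets from them
alone.

## Pipeline and model

The stages, each an exported function, are:

1. **Pileup and variant calling** (`extract_mito_reads()`, `pileup()`,
   `call_variants()`).  Duplicate/secondary/supplementary alignments are
   dropped, bases below Q20 are ignored (the calling literature is typically
   silent on base quality; Q20 is the conventional floor and is
   configurable).  A single-sample caller with VarScan-style thresholds
   emits SNVs with bulk depth ≥ 8, ≥ 2 supporting reads and VAF ≥ 1%.
   Because the bulk mixes donors, candidate *germline* variants are those
   with bulk VAF strictly between 1% and 99%: a variant private to one donor
   of an N-donor pool sits near 1/N, while pool-wide homoplasmies and noise
   sit at the edges.  Indels are out of scope (SNVs only), strands are
   pooled, and every (position, alt) pair is an independent record.
   Local realignment around indels (GATK-style) is a recommended external
   pre-step; any coordinate-sorted indexed BAM is accepted.

2. **Allele count matrices** (`build_matrices()`, `allele_freq()`).  Per
   cell and candidate variant, reference and alternative allele counts; the
   frequency matrix is alt/(alt+ref).  Zero-depth entries are *missing*,
   not 0 — the germline filter counts "cells with a non-zero VAF" among
   observed cells, and collapsing missing into 0 would corrupt that
   denominator.  For clustering input only, missing is imputed as 0
   (an uncovered cell behaves like reference).

3. **Germline selection and genotype clustering** (`filter_germline()`,
   `initial_cluster()`, `cluster_variant_sets()`, `remove_common()`,
   `estimate_alpha()`, wrapped by `fit_genotypes()`).  A variant is kept
   when, among cells with non-zero VAF, more than 50% have VAF > 0.99
   ("VAF above 99%" is read as strictly greater; "non-zero" as strictly
   positive; both cutoffs are arguments).  Cells are clustered into K
   genotypes by K-means on the VAF matrix (or a Gaussian mixture via
   `method = "gmm"`); the same homoplasmy rule applied within each cluster
   yields per-cluster variant sets, and variants occurring in two or more
   sets are removed, leaving *sample-specific* germline variants.  The
   removal threshold defaults to "two or more" rather than the looser
   "more than two" because the doublet model assumes disjoint sets; the
   looser reading is available via `max_sets = 2`.

4. **Doublet scoring** (`posterior_p()`, `score_cells()`,
   `classify_cells()`, `assign_singlets()`).  For cell *c* and cluster
   *i*, the alternative-allele count over cluster-i's specific variants
   observed in *c* follows a binomial with frequency *p*; a conjugate
   Beta(α, 1) prior with α = 1 + the mean per-variant alternative count in
   cluster *i* gives the posterior Beta(α + A1, 1 + A0), summarised by its
   mode (α + A1 − 1)/(α + 1 + A1 + A0 − 2).  `p1` is the posterior for the
   cell's first-fitted cluster (its clustering label; `first = "argmax"`
   switches to the best-scoring cluster), `p2` the highest posterior among
   the others.  A singlet shows p1 ≈ 1 with low p2; a cross-genotype
   doublet carries alternative alleles from two sets and shows
   intermediate p1 with elevated p2.  Cells with p1 > 0.99 and p2 < 0.01
   are singlets, cells with p1 < 0.8 or p2 > 0.2 doublets; the remainder
   take the majority label of their 5 nearest labelled neighbours in
   (p1, p2) space.  Singlets go to the argmax-posterior cluster (ties to
   the lower index, with a warning); doublets are annotated with their
   (first, second) cluster pair; cells covering no specific variant of any
   cluster are reported `unassigned`, never silently dropped.

5. **K estimation and direct mode** (`estimate_k()`, `demux_direct()`).
   When the number of pooled donors is unknown, the mean silhouette width
   over a K-means scan selects it (global maximum; ties to the smaller k).
   When *cells* are hard to cluster — low depth, very unbalanced pools —
   the *variants* are clustered instead by their across-cell frequency
   profiles and each variant group plays the role of a genotype (direct
   mode, see below).

## Choices the write-up left open

Several details are under-determined by the usual description of this
family of methods; the package resolves them as follows, and each is a
documented argument rather than a hidden constant.

**Singlet calls trust p1 (`trust_p1 = TRUE` in `demux_config()`).**
With α = 1 + mean alt count, a pure reference cell scored against a
foreign cluster has posterior mode ≈ (α − 1)/(α − 1 + A0), which at
moderate depth and small variant sets routinely exceeds 0.01 — the
literal "p1 > 0.99 AND p2 < 0.01" singlet rule would then label almost
every cell Unlabeled.  Elevated p2 at high p1 is also produced by shared
somatic mutations rather than a second genotype.  The pipeline therefore
calls any cell with p1 > 0.99 a singlet; `classify_cells()` itself
defaults to the strict two-sided rule so both behaviours are testable.

**Summation over a set's variants.**  The per-set allele summary (A0, A1)
sums reference and alternative counts over the observed specific variants;
this is the only reduction under which the total N = A0 + A1 behaves as a
binomial denominator.

**Clusters with no observed data.**  If a cell covers none of a cluster's
specific variants, that cluster's posterior is undefined (`NA`) and is
excluded from the p2 maximum — a prior-only mode of 1 for α > 1 would
otherwise mark well-covered singlets as doublets purely through coverage
gaps.  A cell with no data for *any* cluster is `unassigned`.

**Carrier-fraction guard (`min_carrier_fraction = 0.5` in the pipeline).**
At ~1× coverage, a foreign cell covered by a single erroneous read has VAF
exactly 1 and counts as "homoplasmic" under the plain ratio rule; with
doublets in a cluster this lets another donor's variants leak into the
cluster's set, after which common-variant removal guts both donors' sets.
The pipeline therefore additionally requires a set variant to be
homoplasmic in more than half of the cluster's *covered* cells — a
criterion that is vacuous when clustering is correct (the fraction is ≈ 1)
and surgical when it is not.  `cluster_variant_sets()` defaults to the
plain printed rule (`min_carrier_fraction = 0`).

**K-means seeding.**  `stats::kmeans` with random restarts frequently
splits a variant-rich donor while merging two variant-poor ones on VAF
block matrices (the dropout noise of a 30-variant donor outweighs the
separation of two 5-variant donors in total within-SS).  The package uses
k-means++ D²-weighted seeding with `n_init = 10` restarts and
`iter.max = 1000`, matching the behaviour of the standard scikit-learn
K-means configuration this family of tools uses.  The clustering seed
(default 42) is exposed everywhere.

**Direct-mode construction.**  Variant profiles are L2-normalised before
clustering so grouping reflects *which* cells carry a variant rather than
how often it was covered; after provisional argmax genotyping under a
uniform prior, the standard per-cluster machinery (homoplasmy rule,
common-variant removal, α estimation) is re-run once on the provisional
labels, which also discards shared haplogroup variants the grouping cannot
place.  `demux_pool()` falls back to direct mode automatically when cell
clustering leaves a cluster without sample-specific variants (the typical
low-depth failure), with a warning; `direct = TRUE` forces it.

**Labels and coordinates.**  Cluster labels are 1-based (R convention);
genome positions are 1-based on the 16,569 bp circle (VCF/rCRS
convention).

## The simulator

`simulate_haplotypes()` draws per-donor private variant sets (default 5-30
variants per donor, pairwise disjoint, positions sampled without
replacement) plus optional variants shared by two or more donors.
`simulate_cells()` then draws, per cell and variant, a Poisson depth with
mean `reads_per_cell × 4/1000` — calibrated so that 1000 mitochondrial
reads per cell correspond to roughly 4× mean coverage — assigns all depth
to the alternative allele at carried variants and to the reference
otherwise, and flips each base independently with probability
`error_rate` (default 0.002, a typical Illumina substitution rate).
Doublets are formed by summing the counts of two uniformly chosen parent
cells (so same-donor doublets occur at rate 1/N in an N-donor pool, as the
cross-genotype arithmetic assumes); parents are removed and the advertised
number of output barcodes is preserved.  `write_sim_sam()` additionally
emits a toy SAM (one single-base read per counted allele, `CB` tags) so
the pileup stage can be exercised end-to-end against a synthetic
16,569 bp reference (`synthetic_mito_reference()`; the real rCRS sequence
is not shipped).

What the simulator does *not* emulate: fragment-length and Tn5 insertion
bias, duplicate structure, the strong positional non-uniformity of real
mitochondrial coverage, NUMT contamination, and heteroplasmy.  Uniform
per-site Poisson dropout at 1× is, if anything, harsher on clustering than
real peaky coverage, but passing tests here do not certify performance on
real libraries with few (< 5) private variants per donor or haploidentical
donors (same maternal lineage), which no mitochondrial method can
separate.  Same-genotype doublets are undetectable by construction; they
cap attainable overall accuracy at 1 − doublet_rate/N.

## Numerical and degenerate-input conventions

* Posterior mode with a zero denominator (uniform prior, no data) is
  missing, not 0.5.
* Posterior ties in singlet assignment break to the lower cluster index
  with a warning.
* An empty cluster yields an empty variant set and a warning; a cluster
  left without specific variants after common-variant removal is a hard
  error (with the direct-mode fallback at the pipeline level).
* KNN rescue requires at least one labelled cell of each class; otherwise
  threshold labels are returned with a warning.
* Reruns with identical inputs, configuration and seed are byte-identical
  (all stochastic steps — simulation, seeding, KNN tie-breaks — run under
  fixed seeds).

## Problem sizes used in the shipped checks

The packaged tests and the results-reproduction script run entirely on the
simulator: pools of 2-8 donors, 15-500 cells per donor, 250-2000
mitochondrial reads per cell (1-8× coverage), 8% doublets and five seeded
replicates per condition — the scale at which the method's behaviour
(perfect recovery when noiseless; graceful degradation at 1×) is fully
visible while a complete run stays in the seconds-to-minutes range.
Evaluation uses permutation-matched accuracy (maximum-weight matching of
clusters onto donors, doublet as its own class), ARI over singlets, and
doublet TPR/FDR/AUC with p2 as the score; the doublet ROC is reported both
over all doublets and restricted to cross-genotype doublets, since
same-genotype doublets are invisible to any genotype-based score.
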