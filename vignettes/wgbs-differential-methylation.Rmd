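---
title: "Methods: two-sample WGBS differential methylation with wgbsdmr"
author: "wgbsdmr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample WGBS differential methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgbsdmr)
library(data.table)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) maps DNA methylation at single-base
resolution: sodium bisulfite converts unmethylated cytosines to uracil (read
as T), while methylated cytosines stay C. Comparing two plant methylomes —
for instance ovules of a female-sterile rice line against its wild-type
progenitor — then amounts to (i) calling the methylation state of every
cytosine in its sequence context (CG, CHG or CHH, with H = A, T or C),
(ii) aggregating calls over biologically meaningful genome elements, and
(iii) testing each element for a difference between the samples.

`wgbsdmr` implements that entire chain, plus a synthetic-data generator with
planted ground truth so every stage can be validated without any external
dataset.

## Models and procedures

### Site-level calling

For each reference cytosine on its strand of origin, aligned read bases C
and T are counted as methylated and unmethylated calls. The conversion rate
$c$ is estimated from a fully unmethylated control sequence as converted
calls over total calls. A site with $m$ methylated calls out of $n$ is
tested against the conversion-failure background with the one-sided
binomial tail $P(X \ge m \mid n, 1 - c)$; Benjamini–Hochberg correction is
applied across all tested sites and sites with $q < 0.05$ (default) are
called methylated. Sites with coverage below 4 (default) are not called.
The calling rule and all three parameters are configurable because
published per-chromosome summary tables rarely state how a site becomes
"methylated"; the binomial-vs-conversion-failure test is the convention of
widely used callers.

### Genome elements

* **Promoters** span TSS−2200 to TSS+500 (2700 bp) on the coding strand,
  partitioned into proximal (P: −200..+500), intermediate (I: −1000..−200)
  and distal (D: −2200..−1000) subregions; minus-strand genes are mirrored.
* **CpG-density classes**: sliding 500-bp windows (step 5 bp) over the
  promoter; HCP if any window has GC ≥ 0.55 and CpG observed/expected
  ≥ 0.75, LCP if no window reaches 0.48, ICP otherwise, with
  observed/expected $= n_{CpG} \cdot L / (n_C \cdot n_G)$. These are the
  Weber-style thresholds; all four numbers are arguments.
* **CpG islands** use the Gardiner-Garden–Frommer criteria (GC ≥ 0.50,
  observed/expected ≥ 0.60, length ≥ 200) applied with position-level
  averaging over all 200-bp windows covering a position, the convention of
  classic CpG-plot implementations. We chose position averaging over raw
  window-union merging because the union systematically over-extends an
  island by up to a window length per side, which distorts island/shore
  assignment. **Shores** are the 2-kb flanks, clipped at neighbouring
  islands (a community convention; islands win when an element overlaps
  both).
* **Exons/introns** come from the gene models with ranks in transcription
  order; **intergenic** space (outside gene bodies and promoters) is tiled
  into 1-kb elements, keeping a final partial tile of ≥ 200 bp. The 1-kb
  unit is our choice: intergenic differential regions need a bounded,
  deterministic testing unit.

### DMR calling

Per element and sample, methylated/unmethylated read calls are summed over
all cytosines of both strands (contexts pooled by default; per-context
aggregation is available). Elements need ≥ 5 covered cytosines and ≥ 20
read calls per sample to be testable. Each testable element is tested with
the Pearson χ² statistic (no continuity correction) on the 2×2 table of
methylated/unmethylated calls; tables with any expected cell < 5 fall back
to Fisher's exact test. One genome-wide BH family covers all testable
elements. The fold change uses Haldane-smoothed ratios
$\tilde r = (m + 0.5)/(m + u + 1)$, so an element with one empty sample
remains defined and an element with both ratios zero can never be called. A
DMR requires $q \le 0.001$ and fold change ≥ 2.0 (both arguments); the
direction is hyper when the sample of interest has the larger smoothed
ratio. A gene containing at least one DMR in its promoter, exons or introns
is a differentially methylated gene (DMG); its direction is the majority of
its DMR directions, with ties reported as mixed.

We test read-call counts rather than site counts because read counts carry
the coverage information the χ² test needs; a site-count aggregation can be
obtained by calling sites first and tabulating calls.

### Enrichment and clustering

Term enrichment of a DMG set against the gene universe uses the
hypergeometric upper tail $P(X \ge k)$ per term (only terms with $k \ge 1$,
$K \ge 1$), BH-corrected; the significance default is $q \le 0.05$.
Methylation-ratio profiles are clustered with average linkage on
$d = 1 - r$ (Pearson) after a $\log_2(x + 0.01)$ transform; constant
profiles are assigned distance 1 and flagged instead of failing. The 0.01
offset is our choice of a small constant that keeps zero ratios finite
without compressing the informative range.

### miRNA promoters and bisulfite-PCR validation

miRNA gene promoters use the same −2200..+500 scheme anchored at the
annotated locus 5′ end. Each testable promoter gets the χ² p-value and the
log2 ratio of smoothed methylation ratios; records are labelled
`**` when $|\log_2 FC| \ge 1$ and $p < 0.01$, `*` when $|\log_2 FC| \ge 1$
and $0.01 < p < 0.05$, otherwise `ns`. The fold-change comparison is
inclusive at 1 because published record sets include loci at exactly
$|\log_2 FC| = 1$ labelled significant; a p-value exactly 0.01 satisfies
neither interval and is labelled `ns`. A promoter/miRNA/target triple is
*coherent* when a hypo-methylated promoter coincides with miRNA
up-regulation and target down-regulation (or the fully mirrored hyper
case).

Bisulfite-PCR clones are aligned gap-free to their amplicon (primers
assumed trimmed); a reference C read as C or T is informative, anything
else counts toward a 20% mismatch cap that excludes a clone. Per-site
percent methylation is nonconverted cytosines over informative clones;
per-context values pool the context's sites.

## The synthetic-data generator

The generator emulates a small plant genome sequenced as a directional
(Lister-style) single-end WGBS experiment:

* **Genome**: i.i.d. background at GC 0.40 (plant-like), with 3 planted
  CpG-dense islands (1200 bp, ~30% CG dinucleotides) per chromosome and a
  separate fully unmethylated 10-kb spike-in control. Default 2 chromosomes
  × 50 kb keeps every test fast while exercising multi-chromosome logic.
* **Annotation**: 6 genes (3 exons each) and 2 single-exon miRNA loci per
  chromosome, on alternating strands, placed so every promoter fits.
* **Methylome**: context means default to mCG 0.40, mCHG 0.32, mCHH 0.14 —
  the levels reported for rice ovules. Each site is methylated-class with
  probability mean/0.7 and draws its level from Beta(7, 3) (mean 0.7), else
  it is exactly 0, so the marginal mean matches the configured context mean
  while truly unmethylated sites exist for calibration tests.
* **Planted DMRs**: elements selected by a plan (promoters, exons, miRNA
  promoters) are overwritten with constant levels 0.8 vs 0.2 — a 4-fold
  truth ratio change, the regime the caller is specified to recover.
* **Reads**: drawn uniformly from both strands; at each origin-strand
  cytosine the read shows C with probability $p + (1-p) \cdot 0.005$
  (conversion failure 0.5%, i.e. >99% conversion efficiency), else T;
  substitution errors at 0.001. Read names carry the truth origin.

What the generator does **not** emulate: sequencing-quality profiles,
PCR duplicates, repeats/transposons, CpG depletion of real plant genomes,
paired ends, or replicate-level variation (libraries are pooled, as in the
study design this emulates). Passing tests therefore demonstrate
correctness of the statistical machinery and coordinate logic, not
robustness to real-data artefacts such as mapping bias in repetitive
regions.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversion happens
  only at format boundaries (GFF3 and SAM are 1-based; BED and bedGraph
  0-based half-open).
* Report percentages are rounded half-up to 2 decimals; totals rows of the
  methylation summary average the per-chromosome percentages unweighted
  (the convention that reproduces published totals), with the pooled-ratio
  alternative available.
* χ² tables with a zero margin return statistic 0 and p = 1, flagged
  degenerate.
* The aligner reduces reads and genome to three letters (C→T for
  plus-strand origin, G→A for minus), finds candidates by an exact 24-bp
  seed and extends allowing ≤ 3 mismatches; uniqueness means exactly one
  best locus, ties are discarded. This is a functional stand-in for a
  production bisulfite aligner, adequate for unique sequence; it does not
  model indels or quality-aware scoring.
* SAM import keeps primary mapped records with MAPQ ≥ 20 (our surrogate
  uniqueness rule, configurable).

## Problem sizes used in the shipped tests

Tests run the generator at 2 × 50 kb (about 48k cytosine sites), 30-fold
site-level coverage for DMR recovery (20 seeds), 200-fold for convergence
checks, and a full read-level pipeline (QC → alignment → calling → DMRs →
enrichment → miRNA → report) at 8-fold coverage. These sizes were chosen to
give stable Monte-Carlo estimates for the planted-truth checks while
keeping the whole suite around a minute.

## Known limitations

* The naive aligner is quadratic in repeat content and keeps the k-mer seed
  index in memory; it is intended for simulated genomes up to a few
  megabases, not real rice chromosomes.
* Contexts are pooled in the element-level test by default; context-specific
  DMRs require running the aggregation per context.
* No SNP-aware calling or M-bias trimming; C/T polymorphisms would read as
  unmethylated cytosines.
* GO term maps are taken as flat annotations; no DAG propagation.
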