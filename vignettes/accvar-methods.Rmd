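---
title: "Methods: cell-type-resolved accessibility modelling and noncoding variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-resolved accessibility modelling and noncoding variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

Most disease-associated variants from genome-wide association studies
(GWAS) of complex eye disease are noncoding, so their interpretation
depends on regulatory context: in which retinal cell types is the locus
accessible, which gene does the element regulate, and does the allele
itself change regulatory activity. `accvar` implements a layered
prioritization of such variants from single-cell multiome data:

1. **Accessibility layer.** Fragment files are converted to
   base-resolution Tn5 insertion tracks per cell type; peaks must be
   reproducible across pseudo-bulk replicates.
2. **Linking layer.** Peaks are connected to genes through
   co-accessibility with promoter peaks and through correlation between
   peak accessibility and gene expression across cell aggregates
   ("predicted target genes"), supplemented by chromatin loops and eQTL
   summary statistics.
3. **Sequence-model layer.** A convolutional network trained on each
   cell type's insertion profile scores the predicted allele effect of
   every SNP on local accessibility.
4. **Ledger.** Each noncoding SNP receives five boolean criteria; SNPs
   meeting most or all are nominated for validation.

A synthetic multiome generator with planted ground truth makes the whole
chain testable at desk scale.

# The synthetic multiome

`synth_config()` fixes the study conditions; `synth_multiome()` draws
the dataset deterministically from one seed.

* **Genome.** Uniform ACGT sequence, by default two chromosomes of
  1.5 Mb. A uniform base model keeps GC matching honest (peaks and
  non-peaks share composition, so the only discriminative sequence
  feature is what we plant).
* **Peaks and motifs.** 200 peaks per cell type (10% shared across all
  types), 200-1,000 bp wide. Each (peak, cell type) carries 1-3 planted
  copies of that cell type's consensus motif; the peak's fragment mass
  is proportional to its copy number, modelling accessibility as a
  monotone readout of TF occupancy. Motif dosage matters: with a single
  copy per peak the peak-vs-background contrast is a binary label that a
  small network can satisfy without ever aligning a filter to the
  motif; dosage variation makes motif strength a regression target and
  forces motif learning. The four PWMs (8-12 bp; OTX-like, homeodomain
  TAAT, bHLH E-box, and a longer zinc-finger-like site) are explicit
  matrices shipped in code.
* **Fragments.** Each cell's fragment left-insertion sites follow a
  per-base Poisson rate: a flat background (140 expected fragments per
  cell genome-wide) plus, per peak of the cell's type, 8 expected
  fragments per cell per motif copy, split 30% uniform-in-peak / 70%
  Gaussian (sd 25 bp) around the motif copies. A drawn site `s` becomes
  the fragment `[s-4, s-4+len)` with `len ~ U(100, 300)`, so the
  +4-shifted start insertion reproduces `s` exactly; the end insertion
  sits at `end-1-4`. Two insertion events per fragment are therefore
  conserved by construction.
* **Cells and QC.** 80 cells per type over 2 donors. QC metrics are
  synthetic per-cell covariates; a configurable 10% of cells violate
  exactly one threshold of the standard multiome gate (200-50,000
  transcripts inclusive; mito < 1%; ribo < 5%; TSS enrichment > 6;
  fragments > 2,500 — the four inequality thresholds strict as usually
  printed, the transcript range read as inclusive; the generator draws
  failing values clear of each boundary so the strictness convention
  never decides a synthetic cell's fate).
* **Expression.** Thirty true peak-gene pairs with TSSs 10-50 kb from
  the peak; a linked gene's per-cell mean expression is
  `1 + 1 x (in-peak insertion count)` with Poisson noise; unlinked genes
  are Poisson(5). Cross-cell-type covariation (a peak accessible only in
  rods drives a gene expressed only in rods) is what the aggregate-level
  correlation detects.
* **SNPs, loops, eQTLs.** Twenty index SNPs with four LD proxies each
  (proxy R^2 drawn in (0.9, 1)); half of the blocks carry a planted
  effect SNP. 70% of effect SNPs disrupt: they sit at the most
  informative position of the single motif copy of a single-copy peak,
  with the alternate allele the lowest-probability base. 30% create:
  a broken motif instance (worst base at the most informative position)
  is planted in background sequence and the alternate allele restores
  the consensus. Loops (5 kb anchors) connect half of the true
  peak-gene pairs; eQTL nominal p-values are drawn from a
  Beta(1, 5000)/Uniform(0,1) mixture (true pairs vs the rest) rather
  than from simulated genotypes, because the pipeline consumes summary
  statistics only.

**What the generator does not emulate:** realistic fragment-length or
Tn5 sequence-bias structure, doublets, ambient RNA, batch effects,
overlapping regulatory grammars, or LD computed from genotypes. Passing
tests therefore demonstrate the correctness and calibration of the
pipeline's logic under a known generative model, not performance on
real retina data.

# Track processing

Insertion tracks are plain per-base count vectors. Reproducible peaks
merge all replicate calls per cell type into union clusters and keep
clusters supported by at least two distinct replicates; the retained
coordinates are the merged union (an explicit, monotone alternative to
summit-based iterative merging, which belongs to peak calling and is out
of scope). TSS normalization divides by total insertion signal within
2 kb of any TSS (union of windows) over a scale constant of 10^4.
GC-matched backgrounds draw, for each peak, a same-width non-peak window
whose GC falls in the same width-0.02 bin, sampling candidates across
chromosomes in proportion to available non-peak sequence; when no
candidate hits the bin the nearest bin is used and counted in a warning.

# Linking

Cells are aggregated by (cell type, donor) — deterministic, desk-scale,
and preserving the across-cell-type covariation that drives the
correlations. Accessibility aggregates are normalized to insertions per
10^4; expression aggregates to counts per 10^4 followed by `log1p`.
Pearson correlation with a strict `> 0.3` cutoff defines both
co-accessibility (peak pairs within 250 kb) and peak-to-gene links
(peak centre to TSS within 250 kb). The 250 kb candidate window is a
convention of linking tools rather than a quantity with a single
canonical value; it is exposed as a parameter. With eight aggregates the
null probability of `r > 0.3` is non-trivial (about 0.2), which the
permutation-null tests account for; real analyses use many more
aggregates. Promoter windows are strand-aware: 2,000 bp upstream to
100 bp downstream of the TSS. A loop links a SNP to a gene when one
anchor overlaps the SNP's containing peak and the other anchor contains
the gene's TSS. eQTL nominal p-values are multiplied by the number of
SNP-gene pairs tested for that SNP (per-SNP Bonferroni, capped at 1)
and called significant below 0.05.

# The sequence model

The model follows the base-resolution profile-network design: one-hot
DNA input, a wide first convolution (width 21), a stack of residual
dilated convolutions (width 3, dilation 2^i), and two heads sharing the
trunk:

* a **profile head** (width-25 convolution, softmax over the centred
  output window) trained with the multinomial negative log likelihood
  (MNLL) of the observed insertion counts; the multinomial coefficient
  is kept in reported values (it is constant in the parameters);
* a **counts head** predicting `log(1 + total counts)` with squared
  error, weighted by 0.1 times the mean total counts per training
  region. The `+1` makes zero-count regions well-defined.

The default geometry is a 2,114 bp input predicting a 1,000 bp centred
window. The counts head reads the trunk through concatenated mean- and
max-pooled features. This is the one deliberate architectural deviation
from the plain global-average-pool head: with desk-scale data a 10 bp
motif contributes O(10/2000) to a mean-pooled feature, and its gradient
is spatially uniform, so the average-pool head converges to the
marginal mean without ever using the motif; the max-pool path makes a
single localized motif able to move the predicted total and routes its
gradient to the motif position. A small decoupled weight decay (1e-4)
on convolution weights further discourages locus memorization.

Training follows the standard augmentation scheme: examples jittered up
to `jitter_bp` each side, a random half reverse-complemented (profile
reversed accordingly), and each batch holding a 10:1 ratio of peak to
GC-matched non-peak regions. Folds are chromosome-disjoint (regions on
one chromosome share a fold); with fewer chromosomes than folds the
split falls back to region level with a warning. The optimizer (Adam,
learning rate, epochs, batch size) is configuration, recorded in the
fitted object; backpropagation is verified against finite differences
to 1e-8 in the test suite.

Desk-scale end-to-end runs train 8 models (4 cell types x 2 folds) with
8 filters, 2 dilated layers and a 1,114/500 bp window geometry — about
a minute per fold — while the package default keeps the full
2,114/1,000 geometry. These problem sizes are stated here as the
package's chosen desk-scale study conditions.

# Allele-effect scoring

For each SNP the input window is centred on the variant; reference and
alternate sequences differ at exactly the centre base. Per (cell type,
fold) the predicted total count is `exp(log_total)`; per cell type the
`log2(alt/ref)` fold changes are averaged over folds. A one-sided
Poisson test compares the fold-averaged alternate count to a Poisson
null with rate the fold-averaged reference count. Two conventions are
explicit options because neither is canonical:

* **Tail direction** — default follows the sign of the predicted change
  (`alt >= ref` tests the upper tail); a fixed upper tail is available.
  The sign-following variant is effectively two-sided, so its null
  rejection rate at level alpha can reach ~2 alpha; calibration claims
  in the tests therefore use the fixed-tail option.
* **Count rounding** — default tests the integer-rounded count (an
  exact discrete tail, matched against brute-force pmf summation); a
  continuous gamma-tail interpolation is available. With the discrete
  tail, an identical-prediction null gives p >= 1/2 exactly at integer
  counts; at non-integer counts rounding can push p slightly below 1/2
  (e.g. lambda = 2.6 rounds to k = 3 with upper tail 0.482). The
  discrete test is conservative: its exact size at alpha = 0.05 is
  below alpha (0.034 at lambda = 20), approaching alpha only as lambda
  grows.

P-values are combined across cell types with Fisher's method
(chi-square with 2k degrees of freedom; inputs clamped at 1e-300) and
Benjamini-Hochberg adjusted **within each scored cohort separately**
(disease SNPs and the background set are separate cohorts). A SNP is
"high-effect" when FDR < 0.01 and the maximum over cell types of the
fold-averaged |log2FC| exceeds 0.5, both strict. The max-over-cell-types
reading reconciles the per-cell-type fold-change rule with the single
combined FDR. Background SNP sets are built by a seeded shuffle of the
candidate universe, removal of coding SNPs, truncation to the first
10,000 entries, then retention of allowed chromosomes — in that order,
so the final set may be slightly smaller than requested.

# The prioritization ledger

Each noncoding SNP receives five criteria: (1) a containing peak is
co-accessible with a promoter peak; (2) a containing peak has a
predicted target gene; (3) the SNP is loop-linked to a gene TSS; (4) it
has a significant eQTL gene; (5) it is a high-effect call. SNPs outside
every peak receive an all-false record even when scored. Criterion 1 is
implemented as "the SNP's peak participates in at least one
co-accessibility link involving a promoter peak", which includes the
case where the SNP's own peak is the promoter peak; the source
definition leaves this open and the inclusive reading is flagged here.
Funnel percentages are rounded half away from zero to one decimal, the
convention used when such tables are printed.

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; SNP tables are
  1-based only at file I/O.
* Nearest-gene ties break by smaller gene start, then lexicographic id.
* Zero-variance peaks or genes are skipped (and counted) in correlation
  linking rather than propagating NaN.
* Profile probabilities are clamped at 1e-12 inside MNLL; Fisher inputs
  at 1e-300.
* Regions whose input window would cross a chromosome edge are dropped
  from training and scoring with an explicit count.
* All randomness flows from user-visible seeds through stream-specific
  derived seeds, so every artifact is reproducible bit-for-bit.

# Known limitations

* The generator's uniform-base genome and consensus-planted motifs are
  far cleaner than real chromatin; sensitivity numbers on synthetic
  data are upper bounds, not forecasts for real variants.
* Aggregation by (cell type, donor) yields few aggregates; correlation
  cutoffs behave differently than with metacell-scale aggregation.
* The desk-scale network is orders of magnitude smaller than
  production accessibility models; it learns planted motifs, not
  regulatory grammar.
* Loops and eQTLs are consumed as given; no loop calling or genotype
  modelling is performed.
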