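# accvar

Cell-type-resolved chromatin accessibility scoring and prioritization of
noncoding disease variants.

## The problem

GWAS of complex eye diseases (age-related macular degeneration,
glaucoma, diabetic retinopathy, myopia, macular telangiectasia) implicate
hundreds of loci, almost all noncoding. Interpreting them requires
knowing (a) in which retinal cell types the locus is open chromatin,
(b) which gene the regulatory element acts on, and (c) whether the
specific allele changes regulatory activity. `accvar` implements that
analysis for single-cell multiome (joint scRNA + scATAC) data:

* per-cell-type base-resolution Tn5 insertion tracks from fragment
  files (+4/−4 shift; two insertion events per fragment), with QC
  filtering and a ≥2-pseudo-bulk-replicate peak reproducibility rule;
* peak–gene evidence: co-accessibility with promoter peaks and
  accessibility–expression correlation across cell aggregates, both at
  a strict Pearson *r* > 0.3; chromatin-loop (SNP peak in one anchor,
  gene TSS in the other) and eQTL evidence (per-SNP Bonferroni,
  `adjusted p = min(1, nominal p × n pairs)`, significant < 0.05);
* a base-resolution convolutional sequence model per cell type
  (profile head trained with multinomial negative log likelihood,
  log-counts head with weighted squared error; 2,114 bp input,
  1,000 bp output window by default) used to score alleles:
  per-cell-type fold-averaged log2(alt/ref) of predicted counts, a
  one-sided Poisson test of the alternate count against the reference
  rate, Fisher combination across cell types, Benjamini–Hochberg
  correction, and a **high-effect** call at FDR < 0.01 with
  max-over-cell-types |log2FC| > 0.5;
* a five-criterion ledger per SNP and per-disease funnel summaries.

A synthetic multiome generator (`synth_multiome()`) with planted motifs,
LD blocks, loops, eQTLs and known effect SNPs provides ground truth so
the entire chain is testable at desk scale. See the methods vignette
(`vignettes/accvar-methods.Rmd`) for the model and every convention.

## Worked example

```r
library(accvar)

mo  <- synth_multiome(synth_config(seed = 1))     # synthetic study
run <- run_pipeline(
  mo,
  model_config(input_len = 1114, output_len = 500, jitter_bp = 250,
               n_filters = 8, n_dilated_layers = 2, n_folds = 2,
               epochs = 60, batch_peaks = 10, learning_rate = 0.02),
  scoring_config(), seed = 1)

run
evaluate_run(run, mo)
```

prints (about eleven minutes of CPU, most of it training the
4 cell-type × 2-fold models):

```
<accvar_run> 288 cells kept | 800 reproducible peaks | 8 models | 100 scored SNPs (10 high-effect)
  high_effect_sensitivity neutral_high_effect_rate background_high_effect_rate
1                       1                        0                  0.01398601
  peak2gene_sensitivity n_effect_snps n_scored
1                     1            10      100
```

Reading: all 10 planted allele-effect SNPs (7 motif-disrupting, 3
motif-creating) are recovered as high-effect calls; none of the 90
neutral disease SNPs and 1.4% of the scored background cohort are
flagged; all 30 planted peak–gene links are recovered at *r* > 0.3. `run$ledger`
holds the per-SNP five-criterion records and `run$funnel` the
per-disease funnel; `autoplot(run$scores)` draws the volcano of allele
effects and `plot_funnel(run$funnel)` the funnel.

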