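#' Run the full prioritization pipeline on a synthetic multiome
#'
#' Chains every stage: QC filtering, pseudo-bulk replicates,
#' reproducibility-filtered peaks, per-cell-type insertion tracks,
#' GC-matched backgrounds, model training per (cell type, fold),
#' aggregation + co-accessibility + peak-to-gene links, promoter peaks,
#' loop links, eQTL adjustment, allele-effect scoring of the disease and
#' background SNP cohorts (BH within each cohort separately), and the
#' five-criterion ledger with its funnel.
#'
#' @param mo A `synth_multiome` (or an equivalently shaped list of
#'   user-supplied components).
#' @param model_cfg A [model_config()]; desk-scale sizes are the
#'   caller's responsibility.
#' @param scoring_cfg A [scoring_config()].
#' @param seed Integer seed for training, backgrounds and the background
#'   SNP shuffle.
#' @param background_n Background SNP cohort size (defaults to the
#'   scoring config's `background_n`, capped at the available universe).
#' @return An `accvar_run` list with every intermediate evidence layer,
#'   the ledger, funnel, and the scored cohorts.
#' @export
run_pipeline <- function(mo, model_cfg = model_config(),
                         scoring_cfg = scoring_config(), seed = 1,
                         background_n = NULL) {
  # --- cells and tracks ---------------------------------------------------
  kept <- qc_filter_cells(mo$cells)
  repro <- reproducible_peaks(mo$replicate_peaks, min_support = 2)
  frags_kept <- mo$fragments[mo$fragments$barcode %in% kept$barcode, ]
  tracks <- cell_type_tracks(frags_kept, kept, mo$chrom_sizes)

  # --- backgrounds + models ----------------------------------------------
  bg <- gc_matched_background(repro, mo$genome, seed = seed)
  bg$cell_type <- repro$cell_type
  models <- train_models(mo$genome, tracks, repro, bg, model_cfg,
                         seed = seed)

  # --- linking layers -----------------------------------------------------
  acc <- peak_cell_counts(frags_kept, repro, kept$barcode)
  rownames(acc) <- repro$peak_id
  groups <- tibble(barcode = kept$barcode,
                   group = paste(kept$cell_type, kept$donor, sep = "."))
  agg <- aggregate_cells(acc, mo$expression[, kept$barcode], groups)
  prom <- promoter_peaks(repro, mo$genes)
  coacc <- coaccessibility(agg$acc, repro)
  p2g <- peak2gene(agg$acc, agg$expr, repro, mo$genes)
  disease_snps <- filter(mo$snps,
                         .data$snp_set %in% c("index", "ld_expanded"))
  noncoding <- filter(disease_snps, !.data$coding)
  loops <- loop_gene_links(noncoding, repro, mo$loops, mo$genes)
  eqtl <- adjust_eqtl(mo$eqtl)

  # --- allele scoring (disease and background cohorts separately) --------
  scores <- score_variants(noncoding, models, mo$genome, scoring_cfg)
  bg_universe <- filter(mo$snps, .data$snp_set == "background")
  n_bg <- min(background_n %||% scoring_cfg$background_n,
              nrow(bg_universe))
  bg_set <- background_snps(bg_universe, n = n_bg, seed = seed,
                            genome = mo$genome)
  bg_scores <- if (nrow(bg_set) > 0) {
    score_variants(bg_set, models, mo$genome, scoring_cfg)
  } else {
    call_high_effect(
      tibble(rsid = character(), cell_type = character(),
             pred_ref = double(), pred_alt = double(),
             mean_log2fc = double(), poisson_p = double()), scoring_cfg)
  }

  # --- ledger -------------------------------------------------------------
  ledger <- build_ledger(noncoding, repro, coacc,
                         prom$peak_id[prom$is_promoter], p2g, loops,
                         eqtl, scores)
  funnel <- summarize_funnel(ledger)

  structure(list(cells_kept = kept, peaks = repro, tracks = tracks,
                 backgrounds = bg, models = models, aggregates = agg,
                 promoters = prom, coaccessibility = coacc,
                 peak2gene = p2g, loop_links = loops, eqtl = eqtl,
                 scores = scores, background_scores = bg_scores,
                 ledger = ledger, funnel = funnel, seed = seed),
            class = "accvar_run")
}

#' @export
print.accvar_run <- function(x, ...) {
  cat(sprintf(
    "<accvar_run> %d cells kept | %d reproducible peaks | %d models | %d scored SNPs (%d high-effect)\n",
    nrow(x$cells_kept), nrow(x$peaks), nrow(x$models), nrow(x$scores),
    sum(x$scores$high_effect)))
  invisible(x)
}

#' Compare a pipeline run against generator ground truth
#'
#' @param run An `accvar_run`.
#' @param mo The `synth_multiome` the run was computed from.
#' @return A one-row tibble: high-effect sensitivity on planted effect
#'   SNPs, high-effect rate among neutral disease SNPs, peak-to-gene
#'   sensitivity over true pairs, loop-link recovery, and eQTL recovery.
#' @export
evaluate_run <- function(run, mo) {
  truth <- mo$truth
  effect_ids <- truth$true_high_effect_snps$rsid
  scored <- run$scores
  neutral <- setdiff(scored$rsid, effect_ids)
  # map true pairs (generator peak ids) onto reproducible peaks by overlap
  true_pk <- mo$peaks[match(truth$true_peak_gene_pairs$peak_id,
                            mo$peaks$peak_id), ]
  ov <- intersect_any(true_pk, run$peaks)
  p2g_hit <- map_lgl(seq_len(nrow(true_pk)), function(i) {
    rp <- run$peaks$peak_id[ov$idx_b[ov$idx_a == i]]
    any(run$peak2gene$peak_id %in% rp &
          run$peak2gene$gene_id ==
            truth$true_peak_gene_pairs$gene_id[i])
  })
  tibble(
    high_effect_sensitivity =
      mean(effect_ids %in% scored$rsid[scored$high_effect]),
    neutral_high_effect_rate =
      mean(neutral %in% scored$rsid[scored$high_effect]),
    background_high_effect_rate =
      if (nrow(run$background_scores) > 0)
        mean(run$background_scores$high_effect) else NA_real_,
    peak2gene_sensitivity = mean(p2g_hit),
    n_effect_snps = length(effect_ids),
    n_scored = nrow(scored))
}

#' @importFrom purrr map_lgl
NULL
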