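#' Per-SNP Bonferroni adjustment of eQTL nominal p-values
#'
#' `adjusted_p = min(1, nominal_p * n_pairs)` where `n_pairs` is the
#' number of SNP-gene pairs tested for that SNP; an association is
#' significant when `adjusted_p < alpha`.
#'
#' @param eqtl Tibble with `rsid`, `gene_id`, `nominal_p`, `n_pairs`.
#' @param alpha Significance level (default 0.05).
#' @return `eqtl` with `adjusted_p` and `significant` columns.
#' @export
adjust_eqtl <- function(eqtl, alpha = 0.05) {
  assert_cols(eqtl, c("rsid", "gene_id", "nominal_p", "n_pairs"))
  if (nrow(eqtl) > 0 && any(eqtl$n_pairs < 1)) {
    abort("adjust_eqtl: n_pairs must be >= 1")
  }
  mutate(eqtl,
         adjusted_p = pmin(1, .data$nominal_p * .data$n_pairs),
         significant = .data$adjusted_p < alpha)
}

#' Five-criterion prioritization ledger
#'
#' Builds one record per noncoding SNP, with the five evidence flags:
#' \describe{
#'   \item{c1_promoter_coaccessible}{a containing peak participates in a
#'     co-accessibility link involving a promoter peak}
#'   \item{c2_has_predicted_target}{a containing peak has a predicted
#'     target gene (peak-to-gene link)}
#'   \item{c3_loop_linked}{the SNP is linked to a gene TSS by a
#'     chromatin loop}
#'   \item{c4_eqtl_significant}{the SNP has a significant eQTL gene}
#'   \item{c5_high_effect}{the SNP is a putative high-effect call}
#' }
#' SNPs outside all peaks get an all-false record (even when scored
#' high-effect). Coding SNPs are excluded.
#'
#' @param snps SNP tibble (`chrom`, `pos`, `rsid`, `disease`, `coding`).
#' @param peaks Peak tibble with `peak_id`, `chrom`, `start`, `end`,
#'   `cell_type`.
#' @param coaccess Co-accessibility links from [coaccessibility()].
#' @param promoter_ids Character vector of promoter peak ids.
#' @param p2g Peak-to-gene links from [peak2gene()].
#' @param loop_links SNP-gene loop links from [loop_gene_links()].
#' @param eqtl Adjusted eQTL tibble from [adjust_eqtl()].
#' @param scores A `variant_scores` tibble ([call_high_effect()]).
#' @return A tibble, one row per SNP: the flags, `n_criteria`,
#'   `accessible_cell_types` and per-criterion gene list-columns.
#' @export
build_ledger <- function(snps, peaks, coaccess, promoter_ids, p2g,
                         loop_links, eqtl, scores) {
  assert_cols(snps, c("chrom", "pos", "rsid", "disease", "coding"))
  # orphan check against the full input set (coding SNPs are known, just
  # excluded from the ledger below)
  layer_rsids <- unique(c(loop_links$rsid, eqtl$rsid, scores$rsid))
  orphans <- setdiff(layer_rsids, snps$rsid)
  if (length(orphans) > 0) {
    abort(sprintf("build_ledger: evidence layers reference unknown rsid(s): %s",
                  paste(head(orphans, 5), collapse = ", ")))
  }
  snps <- filter(snps, !.data$coding)
  hits <- snp_in_peaks(snps, peaks)
  hit_peaks <- tibble(rsid = hits$rsid,
                      peak_id = peaks$peak_id[hits$peak_idx],
                      cell_type = hits$cell_type)
  # peaks participating in a co-accessibility link with a promoter peak
  promoter_partner <- unique(c(
    coaccess$peak1[coaccess$peak2 %in% promoter_ids],
    coaccess$peak2[coaccess$peak1 %in% promoter_ids]))
  eqtl_sig <- filter(eqtl, .data$significant)
  high_rsids <- scores$rsid[scores$high_effect]

  records <- map(seq_len(nrow(snps)), function(i) {
    rs <- snps$rsid[i]
    my_peaks <- hit_peaks[hit_peaks$rsid == rs, ]
    in_peak <- nrow(my_peaks) > 0
    if (!in_peak) {
      return(tibble(rsid = rs, disease = snps$disease[i],
                    accessible_cell_types = list(character()),
                    c1_promoter_coaccessible = FALSE,
                    c2_has_predicted_target = FALSE,
                    c3_loop_linked = FALSE,
                    c4_eqtl_significant = FALSE,
                    c5_high_effect = FALSE,
                    genes_p2g = list(character()),
                    genes_loop = list(character()),
                    genes_eqtl = list(character())))
    }
    g_p2g <- sort(unique(p2g$gene_id[p2g$peak_id %in% my_peaks$peak_id]))
    g_loop <- sort(unique(loop_links$gene_id[loop_links$rsid == rs]))
    g_eqtl <- sort(unique(eqtl_sig$gene_id[eqtl_sig$rsid == rs]))
    tibble(rsid = rs, disease = snps$disease[i],
           accessible_cell_types = list(sort(unique(my_peaks$cell_type))),
           c1_promoter_coaccessible =
             any(my_peaks$peak_id %in% promoter_partner),
           c2_has_predicted_target = length(g_p2g) > 0,
           c3_loop_linked = length(g_loop) > 0,
           c4_eqtl_significant = length(g_eqtl) > 0,
           c5_high_effect = rs %in% high_rsids,
           genes_p2g = list(g_p2g), genes_loop = list(g_loop),
           genes_eqtl = list(g_eqtl))
  })
  out <- bind_rows(records)
  out$n_criteria <- rowSums(out[c("c1_promoter_coaccessible",
                                  "c2_has_predicted_target",
                                  "c3_loop_linked",
                                  "c4_eqtl_significant",
                                  "c5_high_effect")])
  out
}

#' Percentage of a count relative to a denominator, as printed
#'
#' Rounds half-up to one decimal, matching how funnel percentages are
#' conventionally printed (e.g. 1,152 / 7,034 -> 16.4).
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage(s); 0 when the denominator is 0 only if
#'   the numerator is also 0.
#' @export
funnel_percentage <- function(numerator, denominator, digits = 1) {
  pct <- ifelse(denominator == 0,
                ifelse(numerator == 0, 0, NA_real_),
                100 * numerator / denominator)
  round_half_up(pct, digits)
}

#' Per-disease prioritization funnel
#'
#' Counts, per disease, the SNPs at each stage: all ledger SNPs, SNPs in
#' a peak, each criterion, and SNPs meeting all five; percentages are
#' relative to the per-disease ledger size (rounded half-up to one
#' decimal).
#'
#' @param ledger Output of [build_ledger()].
#' @param by_disease Emit one row per disease in addition to the total?
#' @return A tibble with one row per disease plus a `total` row.
#' @export
summarize_funnel <- function(ledger, by_disease = TRUE) {
  tally <- function(df, label) {
    in_peak <- lengths(df$accessible_cell_types) > 0
    tibble(disease = label,
           n_snps = nrow(df),
           n_in_peak = sum(in_peak),
           n_c1 = sum(df$c1_promoter_coaccessible),
           n_c2 = sum(df$c2_has_predicted_target),
           n_c3 = sum(df$c3_loop_linked),
           n_c4 = sum(df$c4_eqtl_significant),
           n_c5 = sum(df$c5_high_effect),
           n_all5 = sum(df$n_criteria == 5),
           pct_in_peak = funnel_percentage(sum(in_peak), nrow(df)),
           pct_high_effect_of_in_peak =
             funnel_percentage(sum(df$c5_high_effect), sum(in_peak)))
  }
  rows <- list()
  if (by_disease) {
    for (d in sort(unique(ledger$disease))) {
      rows[[d]] <- tally(ledger[ledger$disease == d, ], d)
    }
  }
  rows$total <- tally(ledger, "total")
  bind_rows(rows)
}
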