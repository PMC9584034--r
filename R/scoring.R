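#' Variant-scoring thresholds and options
#'
#' @param lfc_threshold High-effect requires max over cell types of
#'   `|mean log2 fold change| >` this (strict; default 0.5).
#' @param fdr_threshold High-effect requires `FDR <` this (strict;
#'   default 0.01).
#' @param background_n Background SNP set size (default 10,000).
#' @param p_floor P-values below this are clamped before Fisher
#'   combination.
#' @param direction One-sided Poisson tail: `"sign"` follows the sign of
#'   the predicted change; `"upper"` always tests the upper tail.
#' @param rounding `"round"` tests the integer-rounded alternate count
#'   (exact discrete tail); `"continuous"` uses the gamma-function
#'   continuation of the Poisson tail.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(lfc_threshold = 0.5, fdr_threshold = 0.01,
                           background_n = 10000, p_floor = 1e-300,
                           direction = c("sign", "upper"),
                           rounding = c("round", "continuous")) {
  stopifnot(lfc_threshold > 0, fdr_threshold > 0, background_n > 0)
  direction <- match.arg(direction)
  rounding <- match.arg(rounding)
  structure(as.list(environment()), class = "scoring_config")
}

#' One-sided Poisson test of a predicted allele count
#'
#' Tests the alternate-allele predicted count against a Poisson null
#' with rate equal to the reference-allele predicted count. With
#' `direction = "sign"`, the tail follows the observed change:
#' `alt >= ref` tests `P(X >= k)`, otherwise `P(X <= k)`, with
#' `k = round(alt)`. With `direction = "upper"` the upper tail is always
#' used. `rounding = "continuous"` replaces the discrete tail by its
#' gamma-function continuation in `alt`.
#'
#' @param alt,ref Predicted counts (vectors recycle; `ref` must be > 0).
#' @param direction,rounding See [scoring_config()].
#' @return P-values in (0, 1].
#' @export
poisson_allele_test <- function(alt, ref, direction = c("sign", "upper"),
                                rounding = c("round", "continuous")) {
  direction <- match.arg(direction)
  rounding <- match.arg(rounding)
  if (any(ref <= 0)) abort("poisson_allele_test: ref count must be > 0")
  n <- max(length(alt), length(ref))
  alt <- rep_len(alt, n); ref <- rep_len(ref, n)
  upper <- if (direction == "upper") rep(TRUE, n) else alt >= ref
  if (rounding == "round") {
    k <- round(alt)
    # P(X >= k) = ppois(k - 1, lower = FALSE); P(X <= k) = ppois(k)
    p <- ifelse(upper, ppois(k - 1, ref, lower.tail = FALSE),
                ppois(k, ref))
  } else {
    # P(X >= x | lambda) = pgamma(lambda, shape = x) for continuous x
    p <- ifelse(upper,
                ifelse(alt <= 0, 1, pgamma(ref, shape = alt)),
                pgamma(ref, shape = alt + 1, lower.tail = FALSE))
  }
  pmin(p, 1)
}

#' Combine p-values with Fisher's method
#'
#' `X^2 = -2 * sum(log p)` referred to a chi-square distribution with
#' `2k` degrees of freedom (upper tail). P-values below `p_floor` are
#' clamped first.
#'
#' @param p Non-empty vector of p-values in (0, 1].
#' @param p_floor Clamp for tiny p-values.
#' @return The combined p-value (equal to `p` when `length(p) == 1`).
#' @export
fisher_combine <- function(p, p_floor = 1e-300) {
  if (length(p) == 0) abort("fisher_combine: empty p-value list")
  if (any(p > 1)) abort("fisher_combine: p-values must be in (0, 1]")
  p <- pmax(pmin(p, 1), p_floor)
  x2 <- -2 * sum(log(p))
  pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement;
#' permutation-equivariant. Authored here so the scoring pipeline's
#' correction is self-contained; agrees with the usual reference
#' implementation.
#'
#' @param p Vector of p-values.
#' @return Adjusted p-values (same order as input).
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Score allele effects on predicted accessibility
#'
#' For each SNP, the model input window is centred at the SNP; reference
#' and alternate sequences differ at exactly the centre base. For every
#' (cell type, fold) model the predicted total count is
#' `exp(log_total)`; per cell type the log2 fold change `log2(alt/ref)`
#' is averaged over folds, and a one-sided Poisson test compares the
#' fold-averaged alternate count to the fold-averaged reference count.
#'
#' @param snps SNP tibble (`chrom`, `pos`, `rsid`, `ref`, `alt`);
#'   validated against `genome`. SNPs whose window leaves the chromosome
#'   are skipped (recorded in attribute `skipped`).
#' @param models Tibble `cell_type`, `fold`, `model` from
#'   [train_models()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param cfg A [scoring_config()].
#' @return A tibble, one row per (rsid, cell_type): `rsid`, `cell_type`,
#'   `pred_ref`, `pred_alt` (fold-averaged counts), `mean_log2fc`,
#'   `poisson_p`.
#' @export
score_alleles <- function(snps, models, genome, cfg = scoring_config()) {
  validate_snps(snps, genome)
  sizes <- chrom_sizes_of(genome)
  input_len <- models$model[[1]]$config$input_len
  half <- input_len %/% 2
  fits <- snps$pos - half >= 0 &
    snps$pos - half + input_len <= sizes$size[match(snps$chrom, sizes$chrom)]
  skipped <- snps$rsid[!fits]
  snps <- snps[fits, ]
  base_rows <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  out <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    s <- snps[i, ]
    win_start <- s$pos - half            # 0-based
    seq <- as.character(Biostrings::subseq(genome[[s$chrom]],
                                           win_start + 1,
                                           win_start + input_len))
    X_ref <- one_hot(seq)
    centre_col <- half + 1L
    X_alt <- X_ref
    X_alt[, centre_col] <- 0
    X_alt[base_rows[[s$alt]], centre_col] <- 1
    per <- models |>
      mutate(
        ref_count = map_dbl(.data$model,
                            ~ exp(predict(.x, X_ref)$log_total)),
        alt_count = map_dbl(.data$model,
                            ~ exp(predict(.x, X_alt)$log_total)))
    cell <- per |>
      group_by(.data$cell_type) |>
      summarise(pred_ref = mean(.data$ref_count),
                pred_alt = mean(.data$alt_count),
                mean_log2fc = mean(log2(.data$alt_count / .data$ref_count)),
                .groups = "drop")
    out[[i]] <- mutate(cell, rsid = s$rsid, .before = 1)
  }
  res <- bind_rows(out)
  if (nrow(res) > 0) {
    res$poisson_p <- poisson_allele_test(res$pred_alt, res$pred_ref,
                                         cfg$direction, cfg$rounding)
  } else {
    res <- tibble(rsid = character(), cell_type = character(),
                  pred_ref = double(), pred_alt = double(),
                  mean_log2fc = double(), poisson_p = double())
  }
  attr(res, "skipped") <- skipped
  res
}

#' Combine per-cell-type allele scores into variant-level calls
#'
#' Fisher-combines the per-cell-type Poisson p-values, applies
#' Benjamini-Hochberg correction within the scored SNP set, and flags
#' putative high-effect SNPs: `FDR < fdr_threshold` and max over cell
#' types `|mean log2 fold change| > lfc_threshold` (both strict).
#'
#' @param cell_scores Output of [score_alleles()].
#' @param cfg A [scoring_config()].
#' @return A `variant_scores` tibble, one row per SNP: `rsid`,
#'   `max_abs_log2fc`, `top_cell_type`, `combined_p`, `fdr`,
#'   `high_effect`, plus a `by_cell_type` list-column.
#' @export
call_high_effect <- function(cell_scores, cfg = scoring_config()) {
  if (nrow(cell_scores) == 0) {
    return(structure(tibble(rsid = character(), max_abs_log2fc = double(),
                            top_cell_type = character(),
                            combined_p = double(), fdr = double(),
                            high_effect = logical(),
                            by_cell_type = list()),
                     class = c("variant_scores", "tbl_df", "tbl", "data.frame")))
  }
  per_snp <- cell_scores |>
    group_by(.data$rsid) |>
    summarise(
      max_abs_log2fc = max(abs(.data$mean_log2fc)),
      top_cell_type = .data$cell_type[which.max(abs(.data$mean_log2fc))],
      combined_p = fisher_combine(.data$poisson_p, cfg$p_floor),
      by_cell_type = list(dplyr::pick("cell_type", "pred_ref",
                                      "pred_alt", "mean_log2fc",
                                      "poisson_p")),
      .groups = "drop")
  per_snp$fdr <- bh_adjust(per_snp$combined_p)
  per_snp$high_effect <- per_snp$fdr < cfg$fdr_threshold &
    per_snp$max_abs_log2fc > cfg$lfc_threshold
  structure(per_snp,
            class = c("variant_scores", "tbl_df", "tbl", "data.frame"))
}

#' Score a SNP set end to end
#'
#' Runs [score_alleles()] then [call_high_effect()]. BH correction is
#' applied within the supplied SNP set only, so disease and background
#' cohorts should be scored in separate calls.
#'
#' @inheritParams score_alleles
#' @return A `variant_scores` tibble (see [call_high_effect()]).
#' @export
score_variants <- function(snps, models, genome, cfg = scoring_config()) {
  cell_scores <- score_alleles(snps, models, genome, cfg)
  res <- call_high_effect(cell_scores, cfg)
  extra <- setdiff(intersect(c("disease", "snp_set"), names(snps)),
                   names(res))
  if (length(extra) > 0) {
    res <- left_join(res, snps[c("rsid", extra)], by = "rsid")
  }
  attr(res, "skipped") <- attr(cell_scores, "skipped")
  res
}

#' Construct a background SNP set
#'
#' Seeded shuffle of the candidate universe, removal of coding SNPs,
#' truncation to the first `n` entries, then retention of SNPs on the
#' allowed chromosomes (in that order, so the result can be smaller than
#' `n`). When a genome is supplied, the GC content of the +/- 50 bp
#' context around each retained SNP is attached for comparison against
#' the disease set.
#'
#' @param snps Candidate SNP tibble (`chrom`, `pos`, `rsid`, `coding`).
#' @param n Number of entries taken after the shuffle (default 10,000).
#' @param seed Integer seed for the shuffle.
#' @param allowed_chroms Chromosomes retained after truncation (default:
#'   all chromosomes present).
#' @param genome Optional genome for context GC.
#' @return The background SNP tibble (with `context_gc` when a genome is
#'   given).
#' @export
background_snps <- function(snps, n = 10000, seed = 1,
                            allowed_chroms = NULL, genome = NULL) {
  assert_cols(snps, c("chrom", "pos", "rsid", "coding"))
  withr::with_seed(derive_seed(seed, "background_snps"), {
    shuffled <- snps[sample(nrow(snps)), ]
  })
  shuffled <- shuffled[!shuffled$coding, ]
  shuffled <- head(shuffled, n)
  if (!is.null(allowed_chroms)) {
    shuffled <- shuffled[shuffled$chrom %in% allowed_chroms, ]
  }
  if (!is.null(genome) && nrow(shuffled) > 0) {
    shuffled$context_gc <- map_dbl(seq_len(nrow(shuffled)), function(i) {
      size <- Biostrings::width(genome[names(genome) == shuffled$chrom[i]])
      st <- max(0, shuffled$pos[i] - 50)
      en <- min(size, shuffled$pos[i] + 51)
      s <- Biostrings::subseq(genome[[shuffled$chrom[i]]], st + 1, en)
      as.numeric(Biostrings::letterFrequency(s, "GC")) / (en - st)
    })
  }
  shuffled
}
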