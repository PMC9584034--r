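#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted sequence model's training history
#'
#' @param x An `accnet` model.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `mnll`, `counts_loss`.
#' @export
tidy.accnet <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted sequence model
#'
#' @param x An `accnet` model.
#' @param ... Unused.
#' @return Tibble with cell type, held-out fold, parameter count,
#'   epochs, final losses and the counts-loss weight.
#' @export
glance.accnet <- function(x, ...) {
  tibble(cell_type = x$cell_type, hold_out_fold = x$hold_out,
         n_parameters = sum(map_int(x$params, length)),
         epochs = nrow(x$history),
         final_loss = tail(x$history$loss, 1),
         final_mnll = tail(x$history$mnll, 1),
         final_counts_loss = tail(x$history$counts_loss, 1),
         counts_loss_weight = x$w_cnt)
}

#' Tidy variant scores into one row per (SNP, cell type)
#'
#' @param x A `variant_scores` tibble.
#' @param ... Unused.
#' @return Long tibble: `rsid`, `cell_type`, `pred_ref`, `pred_alt`,
#'   `mean_log2fc`, `poisson_p`, joined with the SNP-level `combined_p`,
#'   `fdr` and `high_effect`.
#' @export
tidy.variant_scores <- function(x, ...) {
  tidyr::unnest(x[c("rsid", "by_cell_type")], "by_cell_type") |>
    left_join(x[c("rsid", "combined_p", "fdr", "high_effect")],
              by = "rsid")
}

#' One-row summary of a scored SNP cohort
#'
#' @param x A `variant_scores` tibble.
#' @param ... Unused.
#' @return Tibble with cohort size, high-effect count and rate, and the
#'   median |log2FC|.
#' @export
glance.variant_scores <- function(x, ...) {
  tibble(n_snps = nrow(x),
         n_high_effect = sum(x$high_effect),
         high_effect_rate = ifelse(nrow(x) == 0, NA_real_,
                                   mean(x$high_effect)),
         median_max_abs_log2fc = stats::median(x$max_abs_log2fc))
}
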