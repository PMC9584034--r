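#' Volcano-style plot of variant scores
#'
#' Max-over-cell-types mean log2 fold change (signed by the top cell
#' type's direction) against -log10 FDR, high-effect calls highlighted,
#' with the decision thresholds drawn.
#'
#' @param object A `variant_scores` tibble.
#' @param lfc_threshold,fdr_threshold Thresholds to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variant_scores <- function(object, lfc_threshold = 0.5,
                                    fdr_threshold = 0.01, ...) {
  long <- tidy.variant_scores(object)
  top <- long |>
    group_by(.data$rsid) |>
    slice(which.max(abs(.data$mean_log2fc))) |>
    ungroup()
  ggplot2::ggplot(top, ggplot2::aes(x = .data$mean_log2fc,
                                    y = -log10(pmax(.data$fdr, 1e-300)),
                                    colour = .data$high_effect)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(fdr_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean log2 fold change (top cell type)",
                  y = "-log10 FDR", colour = "high effect") +
    ggplot2::theme_minimal()
}

#' Bar chart of the prioritization funnel
#'
#' @param funnel Output of [summarize_funnel()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(funnel) {
  long <- funnel |>
    select("disease", "n_snps", "n_in_peak", "n_c1", "n_c2", "n_c3",
           "n_c4", "n_c5", "n_all5") |>
    tidyr::pivot_longer(-"disease", names_to = "stage",
                        values_to = "count") |>
    mutate(stage = factor(.data$stage,
                          levels = c("n_snps", "n_in_peak", "n_c1",
                                     "n_c2", "n_c3", "n_c4", "n_c5",
                                     "n_all5")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$count,
                                     fill = .data$disease)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "SNPs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Insertion-track browser panel for a region
#'
#' @param tracks Tibble from [cell_type_tracks()].
#' @param chrom,from,to Region (0-based half-open).
#' @param peaks Optional peak tibble to shade.
#' @return A ggplot object.
#' @export
plot_region_tracks <- function(tracks, chrom, from, to, peaks = NULL) {
  dat <- tracks |>
    mutate(signal = map(.data$track, function(tr) {
      tibble(pos = seq(from, to - 1),
             count = tr$counts[[chrom]][(from + 1):to])
    })) |>
    select("cell_type", "signal") |>
    tidyr::unnest("signal")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos,
                                         y = .data$count)) +
    ggplot2::geom_area(fill = "steelblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cell_type)) +
    ggplot2::labs(x = sprintf("%s position (bp)", chrom),
                  y = "Tn5 insertions") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    pk <- peaks[peaks$chrom == chrom & peaks$end > from &
                  peaks$start < to, ]
    if (nrow(pk) > 0) {
      p <- p + ggplot2::annotate("rect", xmin = pk$start, xmax = pk$end,
                                 ymin = -Inf, ymax = Inf, alpha = 0.15,
                                 fill = "orange")
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
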