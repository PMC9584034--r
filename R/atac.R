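#' Quality-control thresholds for multiome nuclei
#'
#' Defaults follow the standard multiome QC gate: 200-50,000 RNA
#' transcripts (inclusive range), <1% mitochondrial reads, <5% ribosomal
#' reads, TSS enrichment >6 and >2,500 ATAC fragments (strict
#' inequalities).
#'
#' @param min_transcripts,max_transcripts Inclusive transcript range.
#' @param max_pct_mito,max_pct_ribo Strict upper bounds, in percent.
#' @param min_tss_enrichment,min_fragments Strict lower bounds.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(min_transcripts = 200, max_transcripts = 50000,
                          max_pct_mito = 1, max_pct_ribo = 5,
                          min_tss_enrichment = 6, min_fragments = 2500) {
  stopifnot(min_transcripts < max_transcripts)
  list(min_transcripts = min_transcripts, max_transcripts = max_transcripts,
       max_pct_mito = max_pct_mito, max_pct_ribo = max_pct_ribo,
       min_tss_enrichment = min_tss_enrichment,
       min_fragments = min_fragments)
}

#' Filter cells on QC metrics
#'
#' Keeps barcodes with `min_transcripts <= n_transcripts <=
#' max_transcripts`, `pct_mito < max_pct_mito`, `pct_ribo < max_pct_ribo`,
#' `tss_enrichment > min_tss_enrichment` and `n_fragments >
#' min_fragments`. The transcript range is inclusive; the other four
#' bounds are strict. Idempotent.
#'
#' @param cells Cell metadata tibble with columns `barcode`,
#'   `n_transcripts`, `pct_mito`, `pct_ribo`, `tss_enrichment`,
#'   `n_fragments`.
#' @param thresholds A list from [qc_thresholds()].
#' @return The subset of `cells` passing all filters.
#' @export
qc_filter_cells <- function(cells, thresholds = qc_thresholds()) {
  assert_cols(cells, c("barcode", "n_transcripts", "pct_mito", "pct_ribo",
                       "tss_enrichment", "n_fragments"))
  filter(cells,
         .data$n_transcripts >= thresholds$min_transcripts,
         .data$n_transcripts <= thresholds$max_transcripts,
         .data$pct_mito < thresholds$max_pct_mito,
         .data$pct_ribo < thresholds$max_pct_ribo,
         .data$tss_enrichment > thresholds$min_tss_enrichment,
         .data$n_fragments > thresholds$min_fragments)
}

#' Base-resolution Tn5 insertion track from fragments
#'
#' Each fragment contributes two insertion events after the +4/-4 Tn5
#' shift: one at `start + 4` and one at `end - 1 - 4` (0-based; the last
#' covered base, shifted inward), each weighted by the fragment's `count`.
#' Shifted positions falling off the chromosome are clipped and counted.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`, `barcode`,
#'   `count`).
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @param barcodes Optional character vector; when given, only fragments
#'   from these barcodes contribute.
#' @return An `insertion_track`: list with `counts` (named list of
#'   per-chromosome numeric vectors; element `i` is base `i - 1`),
#'   `n_clipped`, and `total` (sum of all counts).
#' @export
fragments_to_insertions <- function(fragments, chrom_sizes,
                                    barcodes = NULL) {
  assert_cols(fragments, c("chrom", "start", "end", "barcode", "count"))
  assert_cols(chrom_sizes, c("chrom", "size"))
  if (!is.null(barcodes)) {
    fragments <- filter(fragments, .data$barcode %in% barcodes)
  }
  if (nrow(fragments) > 0 && any(fragments$start < 0)) {
    abort("fragments_to_insertions: negative fragment coordinate")
  }
  counts <- setNames(
    map(chrom_sizes$size, ~ numeric(.x)),
    chrom_sizes$chrom)
  n_clipped <- 0
  for (ch in unique(fragments$chrom)) {
    fr <- fragments[fragments$chrom == ch, ]
    size <- chrom_sizes$size[match(ch, chrom_sizes$chrom)]
    pos <- c(fr$start + 4L, fr$end - 1L - 4L)
    w <- rep(fr$count, 2)
    ok <- pos >= 0L & pos < size
    n_clipped <- n_clipped + sum(w[!ok])
    if (any(ok)) {
      agg <- rowsum(w[ok], pos[ok] + 1L)
      idx <- as.integer(rownames(agg))
      counts[[ch]][idx] <- counts[[ch]][idx] + agg[, 1]
    }
  }
  structure(list(counts = counts, n_clipped = n_clipped,
                 total = sum(map_dbl(counts, sum))),
            class = "insertion_track")
}

#' @export
print.insertion_track <- function(x, ...) {
  cat(sprintf("<insertion_track> %d chromosome(s), %g insertions (%g clipped)\n",
              length(x$counts), x$total, x$n_clipped))
  invisible(x)
}

#' Pseudo-bulk replicate insertion tracks
#'
#' Groups cells by `cell_type` and `donor` (the deterministic stand-in
#' for tool-internal replicate construction) and builds one insertion
#' track per group. Cell types with fewer than two replicate groups are
#' still emitted, with a warning.
#'
#' @param fragments Fragment tibble.
#' @param cells Cell metadata with `barcode`, `cell_type`, `donor`.
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @return A tibble with `cell_type`, `donor`, `n_cells` and a `track`
#'   list-column of `insertion_track` objects.
#' @export
pseudobulk_replicates <- function(fragments, cells, chrom_sizes) {
  assert_cols(cells, c("barcode", "cell_type", "donor"))
  groups <- distinct(cells, .data$cell_type, .data$donor) |>
    arrange(.data$cell_type, .data$donor)
  n_rep <- table(groups$cell_type)
  if (any(n_rep < 2)) {
    warn(sprintf("cell type(s) with a single pseudo-bulk replicate: %s",
                 paste(names(n_rep)[n_rep < 2], collapse = ", ")))
  }
  groups |>
    mutate(
      n_cells = map2_int(.data$cell_type, .data$donor, function(ct, d) {
        sum(cells$cell_type == ct & cells$donor == d)
      }),
      track = map2(.data$cell_type, .data$donor, function(ct, d) {
        bc <- cells$barcode[cells$cell_type == ct & cells$donor == d]
        fragments_to_insertions(fragments, chrom_sizes, barcodes = bc)
      }))
}

#' Aggregate per-cell-type insertion tracks
#'
#' @param fragments Fragment tibble.
#' @param cells Cell metadata with `barcode`, `cell_type`.
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @return Tibble with `cell_type` and a `track` list-column.
#' @export
cell_type_tracks <- function(fragments, cells, chrom_sizes) {
  assert_cols(cells, c("barcode", "cell_type"))
  tibble(cell_type = sort(unique(cells$cell_type))) |>
    mutate(track = map(.data$cell_type, function(ct) {
      bc <- cells$barcode[cells$cell_type == ct]
      fragments_to_insertions(fragments, chrom_sizes, barcodes = bc)
    }))
}

#' Reproducible peaks across pseudo-bulk replicates
#'
#' Within each cell type, replicate peak sets are merged into union
#' clusters; a cluster is retained iff peaks from at least `min_support`
#' distinct replicates overlap it (any shared base). Retained coordinates
#' are the merged union of the supporting intervals, so lowering
#' `min_support` never removes a peak.
#'
#' @param peaks Per-replicate peak tibble with `chrom`, `start`, `end`,
#'   `cell_type`, `replicate`.
#' @param min_support Minimum number of distinct supporting replicates.
#' @return Tibble `chrom`, `start`, `end`, `cell_type`, `n_support`,
#'   `peak_id`.
#' @export
reproducible_peaks <- function(peaks, min_support = 2) {
  if (nrow(peaks) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  cell_type = character(), n_support = integer(),
                  peak_id = character()))
  }
  assert_cols(peaks, c("chrom", "start", "end", "cell_type", "replicate"))
  out <- list()
  for (ct in sort(unique(peaks$cell_type))) {
    p <- peaks[peaks$cell_type == ct, ]
    gr <- to_granges(p)
    merged <- GenomicRanges::reduce(gr)
    hits <- GenomicRanges::findOverlaps(merged, gr)
    support <- tibble(cluster = S4Vectors::queryHits(hits),
                      replicate = p$replicate[S4Vectors::subjectHits(hits)]) |>
      distinct() |>
      dplyr::count(.data$cluster, name = "n_support")
    keep <- support$cluster[support$n_support >= min_support]
    if (length(keep) > 0) {
      m <- merged[keep]
      out[[ct]] <- tibble(
        chrom = as.character(GenomicRanges::seqnames(m)),
        start = GenomicRanges::start(m) - 1L,
        end = GenomicRanges::end(m),
        cell_type = ct,
        n_support = support$n_support[match(keep, support$cluster)])
    }
  }
  res <- bind_rows(out)
  if (nrow(res) > 0) {
    res$peak_id <- sprintf("%s_peak%04d", res$cell_type,
                           stats::ave(seq_len(nrow(res)), res$cell_type,
                                      FUN = seq_along))
  } else {
    res$peak_id <- character()
  }
  res
}

#' Normalize an insertion track by TSS-region signal
#'
#' Divides counts by (total insertions within `tss_window` of any TSS,
#' over the union of windows) / `scale`, so tracks from libraries of
#' different depth become comparable and doubling all counts leaves the
#' normalized track unchanged.
#'
#' @param track An `insertion_track`.
#' @param genes Gene tibble with `chrom`, `tss`.
#' @param tss_window Half-width of the TSS window in bp.
#' @param scale Scale constant (default 1e4).
#' @return An `insertion_track` with real-valued counts; the
#'   normalization factor is stored as attribute `tss_total`.
#' @export
normalize_by_tss <- function(track, genes, tss_window = 2000,
                             scale = 1e4) {
  assert_cols(genes, c("chrom", "tss"))
  tss_total <- 0
  for (ch in names(track$counts)) {
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0) next
    size <- length(track$counts[[ch]])
    win <- GenomicRanges::reduce(GenomicRanges::GRanges(
      ch, IRanges::IRanges(pmax(1L, g$tss + 1L - tss_window),
                           pmin(size, g$tss + 1L + tss_window))))
    for (i in seq_along(win)) {
      tss_total <- tss_total +
        sum(track$counts[[ch]][GenomicRanges::start(win)[i]:GenomicRanges::end(win)[i]])
    }
  }
  if (tss_total <= 0) abort("normalize_by_tss: zero insertions in TSS regions")
  factor <- tss_total / scale
  track$counts <- map(track$counts, ~ .x / factor)
  track$total <- track$total / factor
  attr(track, "tss_total") <- tss_total
  track
}

#' GC-matched non-peak background regions
#'
#' Draws, for every peak, one same-width region from the non-peak genome
#' whose GC fraction falls in the same GC bin (equal-width bins over
#' \[0, 1\]); when no candidate hits the bin, the candidate from the
#' nearest available bin is used with a warning. Backgrounds are disjoint
#' from all peaks by construction.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param genome A [Biostrings::DNAStringSet].
#' @param n_bins Number of GC bins over \[0, 1\] (default 50, width 0.02).
#' @param n_candidates Candidate draws per peak.
#' @param seed Integer seed for candidate sampling.
#' @return Tibble `chrom`, `start`, `end`, `gc`, `peak_gc` with
#'   `nrow(peaks)` rows, aligned to `peaks`.
#' @export
gc_matched_background <- function(peaks, genome, n_bins = 50,
                                  n_candidates = 60, seed = 1) {
  assert_cols(peaks, c("chrom", "start", "end"))
  chrom_sizes <- tibble(chrom = names(genome),
                        size = Biostrings::width(genome))
  # complement of peaks per chromosome
  gaps <- list()
  for (ch in chrom_sizes$chrom) {
    size <- chrom_sizes$size[match(ch, chrom_sizes$chrom)]
    p <- peaks[peaks$chrom == ch, ]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      ch, IRanges::IRanges(p$start + 1L, p$end)))
    gap <- GenomicRanges::gaps(gr, start = 1L, end = size)
    gap <- gap[GenomicRanges::strand(gap) == "*"]
    gaps[[ch]] <- tibble(start = GenomicRanges::start(gap) - 1L,
                         end = GenomicRanges::end(gap))
  }
  # cumulative GC indicator per chromosome -> O(1) window GC
  cumgc <- map(setNames(chrom_sizes$chrom, chrom_sizes$chrom), function(ch) {
    v <- as.integer(Biostrings::letterFrequencyInSlidingView(
      genome[[ch]], 1L, "GC"))
    c(0L, cumsum(v))
  })
  gc_of <- function(ch, start, width) {
    cg <- cumgc[[ch]]
    (cg[start + width + 1L] - cg[start + 1L]) / width
  }
  bin_of <- function(gc) pmin(n_bins, floor(gc * n_bins) + 1L)
  withr::with_seed(derive_seed(seed, "gc_background"), {
    out <- vector("list", nrow(peaks))
    n_off_bin <- 0
    for (i in seq_len(nrow(peaks))) {
      w <- peaks$end[i] - peaks$start[i]
      peak_gc <- gc_of(peaks$chrom[i], peaks$start[i], w)
      target_bin <- bin_of(peak_gc)
      # candidate windows from non-peak gaps, drawn across chromosomes
      # in proportion to feasible gap length
      all_gaps <- bind_rows(imap(gaps, ~ mutate(.x, chrom = .y)))
      all_gaps <- all_gaps[all_gaps$end - all_gaps$start >= w, ,
                           drop = FALSE]
      if (nrow(all_gaps) == 0) {
        abort("gc_matched_background: insufficient non-peak sequence")
      }
      len <- all_gaps$end - all_gaps$start - w + 1L
      k <- sample.int(nrow(all_gaps), n_candidates, replace = TRUE,
                      prob = len)
      st <- all_gaps$start[k] + floor(runif(n_candidates) * len[k])
      cand <- tibble(chrom = all_gaps$chrom[k], start = as.integer(st),
                     end = as.integer(st + w))
      cand$gc <- map_dbl(seq_len(nrow(cand)),
                         ~ gc_of(cand$chrom[.x], cand$start[.x], w))
      cand$bin <- bin_of(cand$gc)
      hit <- which(cand$bin == target_bin)
      if (length(hit) > 0) {
        j <- hit[1]
      } else {
        n_off_bin <- n_off_bin + 1
        j <- which.min(abs(cand$bin - target_bin))
      }
      out[[i]] <- tibble(chrom = cand$chrom[j], start = cand$start[j],
                         end = cand$end[j], gc = cand$gc[j],
                         peak_gc = peak_gc)
    }
    if (n_off_bin > 0) {
      warn(sprintf("gc_matched_background: %d region(s) matched to nearest available GC bin",
                   n_off_bin))
    }
    bind_rows(out)
  })
}

#' @importFrom purrr map2_int
NULL
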