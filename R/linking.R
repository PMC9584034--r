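#' Promoter peaks
#'
#' A peak is a promoter peak iff it overlaps (>= 1 bp) the strand-aware
#' promoter window of some gene: `[tss - upstream, tss + downstream)` for
#' `+` strand genes, `[tss - downstream, tss + upstream)` for `-` strand.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param genes Gene tibble (`chrom`, `tss`, `strand`).
#' @param upstream,downstream Window extents in bp (defaults 2,000 and
#'   100).
#' @return `peaks` with a logical `is_promoter` column and, for promoter
#'   peaks, the `gene_id` of (one of) the promoter(s) overlapped.
#' @export
promoter_peaks <- function(peaks, genes, upstream = 2000,
                           downstream = 100) {
  assert_cols(genes, c("chrom", "tss", "strand"))
  stopifnot(upstream > 0, downstream > 0)
  win <- tibble(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", genes$tss - upstream,
                   genes$tss - downstream),
    end = ifelse(genes$strand == "+", genes$tss + downstream,
                 genes$tss + upstream),
    gene_id = genes$gene_id %||% as.character(seq_len(nrow(genes))))
  win$start <- pmax(0L, as.integer(win$start))
  win$end <- as.integer(win$end)
  hits <- intersect_any(peaks, win)
  out <- mutate(peaks,
                is_promoter = seq_len(nrow(peaks)) %in% hits$idx_a,
                promoter_gene = NA_character_)
  if (nrow(hits) > 0) {
    first <- hits[!duplicated(hits$idx_a), ]
    out$promoter_gene[first$idx_a] <- win$gene_id[first$idx_b]
  }
  out
}

#' Aggregate single cells into pseudo-bulk groups
#'
#' Sums peak accessibility and gene expression over the member cells of
#' each group, then depth-normalizes each aggregate: accessibility to
#' insertions per `scale` (default 1e4), expression to counts per
#' `scale` followed by `log1p`. Invariant under permutation of cells
#' within a group.
#'
#' @param acc Peak x cell accessibility matrix (insertion counts).
#' @param expr Gene x cell expression count matrix (same cell order not
#'   required; columns are matched by barcode name).
#' @param groups Tibble with `barcode` and `group` columns covering the
#'   cells to aggregate.
#' @param scale Depth-normalization constant.
#' @return List with matrices `acc` (peak x aggregate) and `expr`
#'   (gene x aggregate), aggregates in sorted group order.
#' @export
aggregate_cells <- function(acc, expr, groups, scale = 1e4) {
  assert_cols(groups, c("barcode", "group"))
  ids <- sort(unique(groups$group))
  if (length(ids) < 3) {
    abort("aggregate_cells: need >= 3 aggregates for correlation linking")
  }
  agg_mat <- function(m) {
    out <- matrix(0, nrow = nrow(m), ncol = length(ids),
                  dimnames = list(rownames(m), ids))
    for (g in ids) {
      bc <- intersect(groups$barcode[groups$group == g], colnames(m))
      if (length(bc) > 0) {
        out[, g] <- rowSums(m[, bc, drop = FALSE])
      }
    }
    out
  }
  a <- agg_mat(acc)
  e <- agg_mat(expr)
  # depth normalization per aggregate (counts per `scale`)
  a_depth <- colSums(a)
  e_depth <- colSums(e)
  if (any(a_depth == 0) || any(e_depth == 0)) {
    warn("aggregate_cells: aggregate(s) with zero depth left unscaled")
  }
  a <- sweep(a, 2, ifelse(a_depth == 0, 1, a_depth / scale), "/")
  e <- log1p(sweep(e, 2, ifelse(e_depth == 0, 1, e_depth / scale), "/"))
  list(acc = a, expr = e)
}

# Pearson correlation between rows of two matrices for given index
# pairs; rows with zero variance yield NA.
row_pair_cor <- function(m1, m2, i1, i2) {
  map_dbl(seq_along(i1), function(k) {
    x <- m1[i1[k], ]
    y <- m2[i2[k], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    cor(x, y)
  })
}

#' Co-accessibility links between peaks
#'
#' For every pair of peaks on the same chromosome within `max_distance`
#' (centre-to-centre), computes the Pearson correlation of their
#' aggregate accessibility; a link is reported iff the correlation exceeds `cutoff` (strict).
#' Zero-variance peaks are skipped and counted in attribute
#' `n_skipped_zero_var`.
#'
#' @param acc Peak x aggregate accessibility matrix (rownames are peak
#'   ids matching `peaks$peak_id`).
#' @param peaks Peak tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param cutoff Correlation cutoff (default 0.3).
#' @param max_distance Candidate-pair distance bound in bp (default
#'   250,000).
#' @return Tibble `peak1`, `peak2`, `r`, `distance_bp` with `peak1 <
#'   peak2` lexicographically; symmetric by construction.
#' @export
coaccessibility <- function(acc, peaks, cutoff = 0.3,
                            max_distance = 250000) {
  assert_cols(peaks, c("peak_id", "chrom", "start", "end"))
  stopifnot(cutoff > -1, cutoff < 1, max_distance > 0)
  peaks <- peaks[match(rownames(acc), peaks$peak_id), ]
  centre <- floor((peaks$start + peaks$end) / 2)
  pairs <- list()
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    d <- abs(centre[cmb[1, ]] - centre[cmb[2, ]])
    keep <- d <= max_distance
    if (any(keep)) {
      pairs[[ch]] <- tibble(i = cmb[1, keep], j = cmb[2, keep],
                            distance_bp = d[keep])
    }
  }
  pairs <- bind_rows(pairs)
  n_skip <- 0L
  if (nrow(pairs) == 0) {
    out <- tibble(peak1 = character(), peak2 = character(), r = double(),
                  distance_bp = integer())
  } else {
    r <- row_pair_cor(acc, acc, pairs$i, pairs$j)
    n_skip <- sum(is.na(r))
    keep <- !is.na(r) & r > cutoff
    out <- tibble(peak1 = peaks$peak_id[pairs$i[keep]],
                  peak2 = peaks$peak_id[pairs$j[keep]],
                  r = r[keep], distance_bp = pairs$distance_bp[keep])
    swap <- out$peak1 > out$peak2
    tmp <- out$peak1[swap]
    out$peak1[swap] <- out$peak2[swap]
    out$peak2[swap] <- tmp
  }
  attr(out, "n_skipped_zero_var") <- n_skip
  out
}

#' Peak-to-gene links ("predicted target genes")
#'
#' Candidate pairs are (peak, gene TSS) on the same chromosome within
#' `max_distance` (peak centre to TSS). A link is reported iff the
#' Pearson correlation between the peak's aggregate accessibility and
#' the gene's aggregate expression exceeds `cutoff` (strict). Each
#' linked peak is also flagged when its predicted target set differs
#' from its nearest gene.
#'
#' @param acc Peak x aggregate matrix (rownames peak ids).
#' @param expr Gene x aggregate matrix (rownames gene ids).
#' @param peaks Peak tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param genes Gene tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `tss`.
#' @param cutoff Correlation cutoff (default 0.3).
#' @param max_distance Candidate distance bound in bp (default 250,000).
#' @return Tibble `peak_id`, `gene_id`, `r`, `distance_bp`,
#'   `differs_from_nearest`.
#' @export
peak2gene <- function(acc, expr, peaks, genes, cutoff = 0.3,
                      max_distance = 250000) {
  assert_cols(peaks, c("peak_id", "chrom", "start", "end"))
  assert_cols(genes, c("gene_id", "chrom", "start", "end", "tss"))
  peaks <- peaks[match(rownames(acc), peaks$peak_id), ]
  genes_m <- genes[match(rownames(expr), genes$gene_id), ]
  centre <- floor((peaks$start + peaks$end) / 2)
  cand <- list()
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(genes_m$chrom == ch)
    if (length(pi) == 0 || length(gi) == 0) next
    grid <- expand.grid(i = pi, j = gi)
    d <- abs(centre[grid$i] - genes_m$tss[grid$j])
    keep <- d <= max_distance
    if (any(keep)) {
      cand[[ch]] <- tibble(i = grid$i[keep], j = grid$j[keep],
                           distance_bp = d[keep])
    }
  }
  cand <- bind_rows(cand)
  if (nrow(cand) == 0) {
    out <- tibble(peak_id = character(), gene_id = character(),
                  r = double(), distance_bp = integer(),
                  differs_from_nearest = logical())
    attr(out, "n_skipped_zero_var") <- 0L
    return(out)
  }
  r <- row_pair_cor(acc, expr, cand$i, cand$j)
  n_skip <- sum(is.na(r))
  keep <- !is.na(r) & r > cutoff
  out <- tibble(peak_id = peaks$peak_id[cand$i[keep]],
                gene_id = genes_m$gene_id[cand$j[keep]],
                r = r[keep], distance_bp = cand$distance_bp[keep])
  if (nrow(out) > 0) {
    nearest <- nearest_gene(peaks, genes)
    near_of <- setNames(nearest$gene_id, peaks$peak_id)
    out <- out |>
      group_by(.data$peak_id) |>
      mutate(differs_from_nearest =
               !(near_of[[.data$peak_id[1]]] %in% .data$gene_id)) |>
      ungroup()
  } else {
    out$differs_from_nearest <- logical()
  }
  attr(out, "n_skipped_zero_var") <- n_skip
  out
}

#' SNP-gene links through chromatin loops
#'
#' A (SNP, gene) pair is reported iff the SNP lies inside a peak that
#' overlaps one loop anchor and the gene's TSS lies within the other
#' anchor of the same loop. A SNP and TSS in the same anchor are not
#' linked by that anchor.
#'
#' @param snps SNP tibble (`chrom`, `pos`, `rsid`).
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param loops Loop tibble (`chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`).
#' @param genes Gene tibble (`gene_id`, `chrom`, `tss`).
#' @return Tibble `rsid`, `gene_id` (distinct pairs).
#' @export
loop_gene_links <- function(snps, peaks, loops, genes) {
  assert_cols(loops, c("chrom1", "start1", "end1", "chrom2", "start2",
                       "end2"))
  empty <- tibble(rsid = character(), gene_id = character())
  if (nrow(loops) == 0 || nrow(snps) == 0 || nrow(peaks) == 0) {
    return(empty)
  }
  # SNP -> containing peak(s)
  hits <- snp_in_peaks(snps, mutate(peaks, cell_type = "any"))
  if (nrow(hits) == 0) return(empty)
  snp_peaks <- tibble(rsid = hits$rsid, peak = hits$peak_idx)
  anchor <- function(side) {
    tibble(chrom = loops[[paste0("chrom", side)]],
           start = loops[[paste0("start", side)]],
           end = loops[[paste0("end", side)]])
  }
  a1 <- anchor(1); a2 <- anchor(2)
  tsspt <- tibble(chrom = genes$chrom, start = genes$tss,
                  end = genes$tss + 1L)
  link_via <- function(snp_anchor, tss_anchor) {
    ph <- intersect_any(peaks, snp_anchor)   # peak overlaps SNP-side anchor
    th <- intersect_any(tsspt, tss_anchor)   # TSS within gene-side anchor
    if (nrow(ph) == 0 || nrow(th) == 0) return(NULL)
    dplyr::inner_join(snp_peaks,
                      tibble(peak = ph$idx_a, loop = ph$idx_b),
                      by = "peak", relationship = "many-to-many") |>
      dplyr::inner_join(tibble(loop = th$idx_b,
                               gene_id = genes$gene_id[th$idx_a]),
                        by = "loop", relationship = "many-to-many") |>
      select("rsid", "gene_id")
  }
  bind_rows(link_via(a1, a2), link_via(a2, a1)) |> distinct()
}
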