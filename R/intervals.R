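#' Pairs of intervals sharing at least one base
#'
#' Overlap is "any overlapping bases": a pair is reported iff the
#' half-open intervals share >= 1 bp. Backed by [IRanges::findOverlaps()].
#'
#' @param a,b Tibbles with `chrom`, `start`, `end` (0-based half-open).
#' @return A tibble with columns `idx_a`, `idx_b` (row indices into `a`
#'   and `b`).
#' @export
intersect_any <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(idx_a = integer(), idx_b = integer()))
  }
  hits <- GenomicRanges::findOverlaps(to_granges(a), to_granges(b),
                                      minoverlap = 1L)
  tibble(idx_a = S4Vectors::queryHits(hits),
         idx_b = S4Vectors::subjectHits(hits))
}

#' Assign SNPs to the cell types whose peaks contain them
#'
#' A SNP belongs to a cell type iff some peak of that cell type contains
#' its position (0-based, half-open containment).
#'
#' @param snps SNP tibble with `chrom`, `pos`, `rsid`.
#' @param peaks Peak tibble with `chrom`, `start`, `end`, `cell_type`.
#' @return A tibble `rsid`, `cell_type`, `peak_idx` with one row per
#'   (SNP, containing peak); SNPs outside all peaks are absent.
#' @export
snp_in_peaks <- function(snps, peaks) {
  assert_cols(snps, c("chrom", "pos", "rsid"))
  assert_cols(peaks, c("chrom", "start", "end", "cell_type"))
  pts <- tibble(chrom = snps$chrom, start = snps$pos,
                end = snps$pos + 1L)
  hits <- intersect_any(pts, peaks)
  tibble(rsid = snps$rsid[hits$idx_a],
         cell_type = peaks$cell_type[hits$idx_b],
         peak_idx = hits$idx_b)
}

#' Nearest gene for each query interval
#'
#' Distance is the gap between the interval and the gene body (0 when
#' they overlap). Ties are broken deterministically: smaller gene start,
#' then lexicographically smaller `gene_id`.
#'
#' @param peaks Query tibble with `chrom`, `start`, `end`.
#' @param genes Gene tibble with `gene_id`, `chrom`, `start`, `end`.
#' @return A tibble with one row per query: `gene_id`, `distance`.
#' @export
nearest_gene <- function(peaks, genes) {
  assert_cols(genes, c("gene_id", "chrom", "start", "end"))
  if (nrow(genes) == 0) abort("nearest_gene: empty gene set")
  out <- tibble(gene_id = rep(NA_character_, nrow(peaks)),
                distance = rep(NA_integer_, nrow(peaks)))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0) {
      abort(sprintf("nearest_gene: no gene on chromosome %s", ch))
    }
    g <- genes[gi, ]
    for (i in pi) {
      # gap distance between [start,end) intervals; 0 when overlapping
      d <- pmax(0L, pmax(g$start - peaks$end[i], peaks$start[i] - g$end))
      ord <- order(d, g$start, g$gene_id)
      out$gene_id[i] <- g$gene_id[ord[1]]
      out$distance[i] <- d[ord[1]]
    }
  }
  out
}
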