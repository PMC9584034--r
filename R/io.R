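#' Read and write BED intervals
#'
#' BED is 0-based half-open, which is also the package's internal coordinate
#' convention, so coordinates pass through unchanged. Columns beyond the
#' first six are ignored on read.
#'
#' @param path File path.
#' @param x A tibble with at least `chrom`, `start`, `end`; optionally
#'   `name`, `score`, `strand`.
#' @return `read_bed()` returns a tibble with columns `chrom`, `start`,
#'   `end` and, when present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields",
                  which(nf < 3)[1]))
  }
  out <- tibble(
    chrom = map_chr(fields, 1),
    start = suppressWarnings(as.integer(map_chr(fields, 2))),
    end   = suppressWarnings(as.integer(map_chr(fields, 3)))
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 |
                 out$end <= out$start)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d: bad coordinates", bad[1]))
  }
  if (all(nf >= 4)) out$name <- map_chr(fields, 4)
  if (all(nf >= 5)) out$score <- as.numeric(map_chr(fields, 5))
  if (all(nf >= 6)) out$strand <- map_chr(fields, 6)
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  assert_cols(x, c("chrom", "start", "end"))
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # keep a contiguous BED column prefix: stop at the first absent column
  keep <- character()
  for (col in c("chrom", "start", "end", "name", "score", "strand")) {
    if (col %in% cols) keep <- c(keep, col) else break
  }
  readr::write_tsv(x[keep], path, col_names = FALSE)
  invisible(path)
}

#' Read and write BEDPE loop files
#'
#' @param path File path.
#' @param x Tibble with `chrom1,start1,end1,chrom2,start2,end2` (0-based
#'   half-open anchors).
#' @return A tibble of paired anchors.
#' @export
read_bedpe <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom1", "start1", "end1",
                                           "chrom2", "start2", "end2"),
                       col_types = "ciicii", progress = FALSE)
  bad <- which(x$start1 < 0 | x$start2 < 0 | x$end1 <= x$start1 |
                 x$end2 <= x$start2)
  if (length(bad) > 0) abort(sprintf("malformed BEDPE line %d", bad[1]))
  x
}

#' @rdname read_bedpe
#' @export
write_bedpe <- function(x, path) {
  assert_cols(x, c("chrom1", "start1", "end1", "chrom2", "start2", "end2"))
  readr::write_tsv(
    x[c("chrom1", "start1", "end1", "chrom2", "start2", "end2")],
    path, col_names = FALSE)
  invisible(path)
}

#' Read a 10x-style fragments file
#'
#' Five tab-separated columns: chrom, start, end, barcode, count, with BED
#' coordinates (0-based half-open).
#'
#' @param path File path (plain text TSV).
#' @param x Tibble of fragments.
#' @return A tibble with columns `chrom`, `start`, `end`, `barcode`,
#'   `count`.
#' @export
read_fragments <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                           "barcode", "count"),
                       col_types = "ciici", progress = FALSE)
  if (any(x$start < 0)) {
    abort(sprintf("fragment line %d: negative coordinate",
                  which(x$start < 0)[1]))
  }
  if (any(x$end <= x$start)) {
    abort(sprintf("fragment line %d: end <= start",
                  which(x$end <= x$start)[1]))
  }
  x
}

#' @rdname read_fragments
#' @export
write_fragments <- function(x, path) {
  assert_cols(x, c("chrom", "start", "end", "barcode", "count"))
  readr::write_tsv(x[c("chrom", "start", "end", "barcode", "count")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Read and write SNP tables
#'
#' The on-disk table is 1-based (`pos_1based`); internally positions are
#' 0-based (`pos`). Columns: chrom, pos_1based, rsid, ref, alt, disease,
#' snp_set (index / ld_expanded / background), r2, coding.
#'
#' @param path File path.
#' @param x Internal SNP tibble (0-based `pos`).
#' @param genome Optional [Biostrings::DNAStringSet]; when supplied, each
#'   SNP's `ref` allele is checked against the genome base at `pos`.
#' @return `read_snp_table()` returns a tibble with a 0-based `pos` column.
#' @export
read_snp_table <- function(path, genome = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos_1based = readr::col_integer(),
    rsid = readr::col_character(), ref = readr::col_character(),
    alt = readr::col_character(), disease = readr::col_character(),
    snp_set = readr::col_character(), r2 = readr::col_double(),
    coding = readr::col_logical()), progress = FALSE)
  if (any(x$pos_1based < 1)) {
    abort(sprintf("SNP line %d: position < 1", which(x$pos_1based < 1)[1]))
  }
  x <- mutate(x, pos = .data$pos_1based - 1L) |>
    select(-"pos_1based") |>
    select("chrom", "pos", dplyr::everything())
  validate_snps(x, genome)
}

#' @rdname read_snp_table
#' @export
write_snp_table <- function(x, path) {
  assert_cols(x, c("chrom", "pos", "rsid", "ref", "alt", "disease",
                   "snp_set", "r2", "coding"))
  out <- mutate(x, pos_1based = .data$pos + 1L) |>
    select("chrom", "pos_1based", "rsid", "ref", "alt", "disease",
           "snp_set", "r2", "coding")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Validate a SNP tibble
#'
#' Checks single-base ref/alt, ref != alt, and (when a genome is given)
#' that ref matches the genome base at the 0-based position.
#'
#' @inheritParams read_snp_table
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_snps <- function(x, genome = NULL) {
  assert_cols(x, c("chrom", "pos", "rsid", "ref", "alt"))
  bases <- c("A", "C", "G", "T")
  bad <- which(!(x$ref %in% bases) | !(x$alt %in% bases))
  if (length(bad) > 0) {
    abort(sprintf("SNP %s: ref/alt must be a single base A/C/G/T",
                  x$rsid[bad[1]]))
  }
  if (any(x$ref == x$alt)) {
    abort(sprintf("SNP %s: ref equals alt", x$rsid[which(x$ref == x$alt)[1]]))
  }
  if (!is.null(genome)) {
    for (ch in unique(x$chrom)) {
      idx <- which(x$chrom == ch)
      seq <- genome[[ch]]
      obs <- as.character(Biostrings::extractAt(
        seq, IRanges::IRanges(x$pos[idx] + 1L, width = 1L)))
      mism <- idx[obs != x$ref[idx]]
      if (length(mism) > 0) {
        abort(sprintf("SNP %s: ref allele %s does not match genome base %s",
                      x$rsid[mism[1]], x$ref[mism[1]],
                      obs[which(obs != x$ref[idx])[1]]))
      }
    }
  }
  invisible(x)
}

#' Read and write eQTL summary tables
#'
#' Columns: rsid, gene_id, nominal_p, n_pairs (number of SNP-gene pairs
#' tested for that SNP).
#'
#' @param path File path.
#' @param x eQTL tibble.
#' @return A tibble.
#' @export
read_eqtl <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    rsid = readr::col_character(), gene_id = readr::col_character(),
    nominal_p = readr::col_double(), n_pairs = readr::col_integer()),
    progress = FALSE)
}

#' @rdname read_eqtl
#' @export
write_eqtl <- function(x, path) {
  assert_cols(x, c("rsid", "gene_id", "nominal_p", "n_pairs"))
  readr::write_tsv(x[c("rsid", "gene_id", "nominal_p", "n_pairs")], path)
  invisible(path)
}

#' @importFrom purrr map_chr
NULL
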