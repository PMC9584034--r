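#' Round half away from zero
#'
#' Percentages in summary tables are rounded half-up to a fixed number of
#' decimals (so 16.35 -> 16.4), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a child seed from a base seed and a stream label; keeps every
# source of randomness tied to one user-visible seed while decoupling the
# streams from each other. Result stays below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629L)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
to_granges <- function(df) {
  assert_cols(df, c("chrom", "start", "end"))
  # internal coordinates are 0-based half-open; GRanges is 1-based closed
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}
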