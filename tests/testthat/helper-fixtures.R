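# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

# A small multiome: fast to generate, large enough to exercise QC,
# reproducibility, linking and SNP layers (not used for model training).
tiny_config <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(seed = seed,
         n_chroms = 2,
         chrom_length_bp = 120000,
         n_cells_per_type = 40,
         n_peaks_per_type = 8,
         n_genes = 24,
         n_linked_pairs = 10,
         n_index_snps = 6,
         ld_block_size = 3,
         effect_snp_fraction = 0.5,
         gain_fraction = 0.3,
         n_background_snps = 60),
    list(...))
  do.call(synth_config, args)
}

tiny_mo <- function() {
  if (is.null(.fixture_env$mo)) {
    .fixture_env$mo <- suppressWarnings(synth_multiome(tiny_config()))
  }
  .fixture_env$mo
}

# A multiome sized for quick model training: more peaks per type so the
# motif (not individual loci) is the learnable signal.
train_mo <- function() {
  if (is.null(.fixture_env$train_mo)) {
    .fixture_env$train_mo <- suppressWarnings(synth_multiome(tiny_config(
      seed = 7, chrom_length_bp = 500000, n_peaks_per_type = 50,
      n_cells_per_type = 40, n_genes = 20, n_linked_pairs = 8,
      n_background_snps = 40)))
  }
  .fixture_env$train_mo
}

# Random interval tibble on a small chromosome set.
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4,
                             max_width = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE))
}

# O(n*m) overlap oracle for half-open intervals.
brute_overlaps <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(idx_a = integer(), idx_b = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(idx_a = m[, 1], idx_b = m[, 2])
}

sort_pairs <- function(x) x[order(x$idx_a, x$idx_b), ]

# Desk-scale model configuration used for end-to-end training runs: the
# paper-scale 2,114/1,000 geometry stays the package default; end-to-end
# checks train shorter windows so 4 cell types x 2 folds fit in minutes.
desk_model_config <- function() {
  model_config(input_len = 1114, output_len = 500, jitter_bp = 250,
               n_filters = 8, n_dilated_layers = 2, n_folds = 2,
               epochs = 60, batch_peaks = 10, learning_rate = 0.02)
}

# Full study-condition pipeline run (default generator conditions),
# computed once and shared by the end-to-end acceptance checks.
acceptance_run <- function() {
  if (is.null(.fixture_env$acc_run)) {
    mo <- suppressWarnings(synth_multiome(synth_config(seed = 1)))
    run <- suppressWarnings(
      run_pipeline(mo, desk_model_config(), scoring_config(), seed = 1))
    .fixture_env$acc_run <- list(mo = mo, run = run,
                                 eval = evaluate_run(run, mo))
  }
  .fixture_env$acc_run
}
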