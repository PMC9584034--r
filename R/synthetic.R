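#' Configuration for the synthetic multiome generator
#'
#' Defines a miniature joint ATAC + RNA experiment with known ground
#' truth: a random genome, cell-type-specific peaks driven by planted PWM
#' motifs, per-cell fragments from a per-base Poisson rate, expression
#' correlated with linked-peak accessibility, LD-structured SNPs with
#' planted motif-disrupting/creating alleles, chromatin loops and eQTL
#' summary statistics.
#'
#' @param seed Integer seed; every downstream draw derives from it.
#' @param n_chroms,chrom_length_bp Genome shape. `chrom_length_bp` must be
#'   at least `10 * input_len`.
#' @param cell_types Cell-type labels; each is assigned one motif from
#'   `motifs` (recycled in order).
#' @param n_cells_per_type,n_donors Cells per type, split evenly over
#'   donors (donors double as pseudo-bulk replicates downstream).
#' @param motifs Named list of PWMs (see [default_motifs()]).
#' @param n_peaks_per_type Accessible peaks per cell type.
#' @param shared_peak_fraction Fraction of each type's peaks that are
#'   shared across all cell types.
#' @param peak_width_range Min/max peak width in bp.
#' @param replicate_jitter_bp Max absolute shift applied to each
#'   per-replicate copy of a peak call.
#' @param n_genes,n_linked_pairs Gene count and number of true
#'   peak-gene links (linked TSSs are placed 10-50 kb from their peak).
#' @param loop_fraction Fraction of true peak-gene pairs connected by a
#'   chromatin loop (5 kb anchors).
#' @param n_index_snps,ld_block_size Index SNPs and LD proxies per index
#'   SNP (proxy R^2 drawn > 0.9).
#' @param effect_snp_fraction Fraction of index loci whose LD block
#'   carries a planted allele-effect SNP.
#' @param gain_fraction Of the effect SNPs, the fraction that create a
#'   motif (alternate allele restores a planted broken instance in
#'   background sequence); the rest disrupt an in-peak motif (alternate =
#'   lowest-probability base at the most informative PWM position).
#' @param qc_fail_fraction Fraction of cells given exactly one failing QC
#'   metric.
#' @param background_fragments_per_cell,peak_fragments_per_cell Expected
#'   per-cell fragments from genome-wide background and from each
#'   full-strength peak; together they set the per-base Poisson rate.
#' @param motif_strength Multiplier on every peak's fragment mass
#'   (expected in-peak insertion counts scale linearly with it).
#' @param motif_copies_range Min/max motif copies planted per (peak,
#'   cell type); a peak's fragment mass scales with its copy number, so
#'   accessibility tracks motif dosage.
#' @param motif_mass,motif_sd Share of a peak's mass concentrated in
#'   Gaussians around the motif copies, and their sd in bp.
#' @param frag_length_range Fragment length range in bp.
#' @param expr_slope,expr_intercept Linked-gene expression is
#'   `intercept + slope * per-cell peak insertion count`.
#' @param expr_noise Either "poisson" (counts drawn Poisson at that mean)
#'   or "none" (rounded mean, used for exactness checks).
#' @param expr_base Mean expression of unlinked genes.
#' @param n_background_snps Size of the neutral background SNP universe.
#' @param coding_fraction Fraction of LD and background SNPs flagged as
#'   coding (placed inside gene bodies).
#' @param diseases Disease labels cycled over index loci.
#' @param input_len Model input length used only to validate margins.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_chroms = 2,
                         chrom_length_bp = 1.5e6,
                         cell_types = c("rod", "cone", "muller_glia",
                                        "bipolar"),
                         n_cells_per_type = 80,
                         n_donors = 2,
                         motifs = default_motifs(),
                         n_peaks_per_type = 200,
                         shared_peak_fraction = 0.1,
                         peak_width_range = c(200, 1000),
                         replicate_jitter_bp = 25,
                         n_genes = 80,
                         n_linked_pairs = 30,
                         loop_fraction = 0.5,
                         n_index_snps = 20,
                         ld_block_size = 4,
                         effect_snp_fraction = 0.5,
                         gain_fraction = 0.3,
                         qc_fail_fraction = 0.1,
                         background_fragments_per_cell = 140,
                         peak_fragments_per_cell = 8,
                         motif_strength = 1,
                         motif_copies_range = c(1, 3),
                         motif_mass = 0.7,
                         motif_sd = 25,
                         frag_length_range = c(100, 300),
                         expr_slope = 1,
                         expr_intercept = 1,
                         expr_noise = c("poisson", "none"),
                         expr_base = 5,
                         n_background_snps = 300,
                         coding_fraction = 0.05,
                         diseases = c("AMD", "glaucoma", "DR", "myopia",
                                      "MacTel"),
                         input_len = 2114) {
  if (chrom_length_bp < 10 * input_len) {
    abort(sprintf("chrom_length_bp (%g) must be at least 10 x input_len (%d)",
                  chrom_length_bp, 10 * input_len))
  }
  if (n_cells_per_type < 1) abort("n_cells_per_type must be >= 1")
  expr_noise <- match.arg(expr_noise)
  cfg <- as.list(environment())
  cfg$chrom_length_bp <- as.integer(chrom_length_bp)
  # one motif per cell type, recycled
  cfg$cell_type_motifs <- setNames(
    names(motifs)[(seq_along(cell_types) - 1) %% length(motifs) + 1],
    cell_types)
  structure(cfg, class = "synth_config")
}

#' Generate a random genome
#'
#' Uniform ACGT bases; deterministic given the config seed.
#'
#' @param cfg A [synth_config()].
#' @return A named [Biostrings::DNAStringSet] (`chr1`, `chr2`, ...).
#' @export
generate_genome <- function(cfg) {
  withr::with_seed(derive_seed(cfg$seed, "genome"), {
    seqs <- vapply(seq_len(cfg$n_chroms), function(i) {
      paste(sample(c("A", "C", "G", "T"), cfg$chrom_length_bp,
                   replace = TRUE), collapse = "")
    }, character(1))
  })
  gs <- Biostrings::DNAStringSet(seqs)
  names(gs) <- paste0("chr", seq_len(cfg$n_chroms))
  gs
}

#' Chromosome sizes of a genome
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return Tibble with `chrom`, `size`.
#' @export
chrom_sizes_of <- function(genome) {
  tibble(chrom = names(genome), size = Biostrings::width(genome))
}

# Replace genome[chrom][start0, start0+nchar(seq)) with seq (0-based).
write_sequence <- function(genome, chrom, start0, seq) {
  genome[[chrom]] <- Biostrings::replaceAt(
    genome[[chrom]],
    IRanges::IRanges(start0 + 1L, width = nchar(seq)),
    Biostrings::DNAStringSet(seq)[[1]])
  genome
}

#' Plant peaks and motif instances into a genome
#'
#' Samples non-overlapping peak loci (a configurable fraction shared by
#' all cell types, the rest type-specific), writes one consensus motif
#' instance per (peak, cell type) into the genome, emits per-replicate
#' jittered copies of each peak call so the reproducibility filter is
#' exercised, and additionally plants broken background motif instances
#' (one base off consensus, outside any peak) to host motif-creating
#' SNPs. Peaks that would overlap a chromosome edge are dropped with a
#' warning.
#'
#' @param genome A [Biostrings::DNAStringSet] from [generate_genome()].
#' @param cfg A [synth_config()].
#' @return List with elements `genome` (motifs written in), `peaks`
#'   (one row per peak x cell type: `peak_id`, `locus_id`, `chrom`,
#'   `start`, `end`, `cell_type`, `strength`), `replicate_peaks` (jittered
#'   per-(cell type, donor) calls), and `motif_instances` (`chrom`,
#'   `start`, `end`, `motif`, `cell_type`, `peak_id`, `kind` in
#'   {"intact", "broken_background"}).
#' @export
plant_peaks_and_motifs <- function(genome, cfg) {
  sizes <- chrom_sizes_of(genome)
  margin <- as.integer(cfg$input_len / 2 + 600 + 500)
  min_gap <- 800L
  n_types <- length(cfg$cell_types)
  n_shared <- round(cfg$shared_peak_fraction * cfg$n_peaks_per_type)
  n_specific <- cfg$n_peaks_per_type - n_shared
  n_loci <- n_shared + n_types * n_specific
  n_effect <- round(cfg$effect_snp_fraction * cfg$n_index_snps)
  n_gain <- round(cfg$gain_fraction * n_effect)

  withr::with_seed(derive_seed(cfg$seed, "peaks"), {
    # sample non-overlapping loci with a margin from chromosome edges
    loci <- tibble(chrom = character(), start = integer(), end = integer())
    attempts <- 0
    while (nrow(loci) < n_loci && attempts < 50 * n_loci) {
      attempts <- attempts + 1
      w <- sample(seq(cfg$peak_width_range[1], cfg$peak_width_range[2]), 1)
      ci <- sample.int(nrow(sizes), 1, prob = sizes$size)
      size <- sizes$size[ci]
      if (size - 2 * margin - w <= 0) next
      st <- margin + sample.int(size - 2L * margin - w, 1)
      ok <- !any(loci$chrom == sizes$chrom[ci] &
                   loci$start < st + w + min_gap &
                   loci$end + min_gap > st)
      if (ok) {
        loci <- bind_rows(loci, tibble(chrom = sizes$chrom[ci],
                                       start = st, end = st + w))
      }
    }
    if (nrow(loci) < n_loci) {
      abort("plant_peaks_and_motifs: could not place all peak loci; reduce n_peaks_per_type or enlarge the genome")
    }
    dropped <- loci$start < 0 | loci$end > sizes$size[match(loci$chrom, sizes$chrom)]
    if (any(dropped)) {
      warn(sprintf("%d peak locus(i) overlapping a chromosome edge dropped",
                   sum(dropped)))
      loci <- loci[!dropped, ]
    }
    loci$locus_id <- sprintf("locus%03d", seq_len(nrow(loci)))

    # assign loci: first n_shared shared by all types, rest round-robin
    assign <- vector("list", nrow(loci))
    for (i in seq_len(nrow(loci))) {
      if (i <= n_shared) {
        assign[[i]] <- cfg$cell_types
      } else {
        assign[[i]] <- cfg$cell_types[((i - n_shared - 1) %% n_types) + 1]
      }
    }
    peaks <- tibble(
      locus_id = rep(loci$locus_id, lengths(assign)),
      chrom = rep(loci$chrom, lengths(assign)),
      start = rep(loci$start, lengths(assign)),
      end = rep(loci$end, lengths(assign)),
      cell_type = unlist(assign))
    peaks$peak_id <- sprintf("%s_%s", peaks$locus_id, peaks$cell_type)
    peaks$n_copies <- sample(
      seq(cfg$motif_copies_range[1], cfg$motif_copies_range[2]),
      nrow(peaks), replace = TRUE)
    peaks$strength <- peaks$n_copies

    # plant n_copies consensus motif instances per (locus, cell type),
    # spaced around the peak centre (offset further when shared)
    inst <- vector("list", nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      motif_name <- cfg$cell_type_motifs[[peaks$cell_type[i]]]
      pwm <- cfg$motifs[[motif_name]]
      w_m <- ncol(pwm)
      share <- which(peaks$locus_id == peaks$locus_id[i])
      k <- match(i, share)
      base_centre <- floor((peaks$start[i] + peaks$end[i]) / 2) +
        as.integer((k - (length(share) + 1) / 2) * 30 * cfg$motif_copies_range[2])
      cons <- attr(pwm, "consensus")
      rows <- vector("list", peaks$n_copies[i])
      for (cp in seq_len(peaks$n_copies[i])) {
        centre <- base_centre +
          as.integer((cp - (peaks$n_copies[i] + 1) / 2) * 30)
        m_start <- centre - floor(w_m / 2)
        m_start <- max(peaks$start[i] + 5L,
                       min(m_start, peaks$end[i] - w_m - 5L))
        genome <- write_sequence(genome, peaks$chrom[i], m_start, cons)
        rows[[cp]] <- tibble(chrom = peaks$chrom[i], start = m_start,
                             end = m_start + w_m, motif = motif_name,
                             cell_type = peaks$cell_type[i],
                             peak_id = peaks$peak_id[i], kind = "intact")
      }
      inst[[i]] <- bind_rows(rows)
    }
    motif_instances <- bind_rows(inst)

    # broken background instances for motif-creating SNPs
    if (n_gain > 0) {
      broken <- vector("list", n_gain)
      for (g in seq_len(n_gain)) {
        ct <- cfg$cell_types[((g - 1) %% n_types) + 1]
        motif_name <- cfg$cell_type_motifs[[ct]]
        pwm <- cfg$motifs[[motif_name]]
        w_m <- ncol(pwm)
        repeat {
          ci <- sample.int(nrow(sizes), 1, prob = sizes$size)
          size <- sizes$size[ci]
          st <- margin + sample.int(size - 2L * margin - w_m, 1)
          clear <- !any(loci$chrom == sizes$chrom[ci] &
                          loci$start < st + w_m + min_gap &
                          loci$end + min_gap > st)
          if (clear) break
        }
        j <- pwm_max_info_position(pwm)
        cons <- strsplit(attr(pwm, "consensus"), "")[[1]]
        cons[j] <- pwm_worst_base(pwm, j)
        genome <- write_sequence(genome, sizes$chrom[ci], st,
                                 paste(cons, collapse = ""))
        broken[[g]] <- tibble(chrom = sizes$chrom[ci], start = st,
                              end = st + w_m, motif = motif_name,
                              cell_type = ct, peak_id = NA_character_,
                              kind = "broken_background")
      }
      motif_instances <- bind_rows(motif_instances, bind_rows(broken))
    }

    # per-replicate jittered peak calls: one copy per (cell type, donor)
    reps <- vector("list", 0)
    for (d in seq_len(cfg$n_donors)) {
      shift <- sample(seq(-cfg$replicate_jitter_bp, cfg$replicate_jitter_bp),
                      nrow(peaks), replace = TRUE)
      reps[[d]] <- mutate(peaks,
                          start = .data$start + shift,
                          end = .data$end + shift,
                          replicate = sprintf("donor%d", d))
    }
    replicate_peaks <- bind_rows(reps) |>
      select("chrom", "start", "end", "cell_type", "replicate",
             "locus_id", "peak_id")
  })
  list(genome = genome, peaks = peaks, replicate_peaks = replicate_peaks,
       motif_instances = motif_instances)
}

# Place genes: linked genes 10-50 kb from their peak's centre, the rest
# uniform outside peaks. Returns genes + the true peak-gene pairs.
place_genes <- function(peaks, sizes, cfg) {
  withr::with_seed(derive_seed(cfg$seed, "genes"), {
    n_linked <- min(cfg$n_linked_pairs, nrow(peaks))
    linked_rows <- sample.int(nrow(peaks), n_linked)
    genes <- vector("list", cfg$n_genes)
    pairs <- vector("list", n_linked)
    for (i in seq_len(cfg$n_genes)) {
      gid <- sprintf("g%04d", i)
      strand <- sample(c("+", "-"), 1)
      if (i <= n_linked) {
        p <- peaks[linked_rows[i], ]
        centre <- floor((p$start + p$end) / 2)
        d <- sample(c(-1, 1), 1) * sample(seq(10000L, 50000L), 1)
        tss <- centre + d
        chrom <- p$chrom
        pairs[[i]] <- tibble(peak_id = p$peak_id, gene_id = gid)
      } else {
        # unlinked: uniform position outside every peak
        repeat {
          ci <- sample.int(nrow(sizes), 1, prob = sizes$size)
          tss <- 5000L + sample.int(sizes$size[ci] - 10000L, 1)
          chrom <- sizes$chrom[ci]
          if (!any(peaks$chrom == chrom & peaks$start <= tss &
                     peaks$end > tss)) break
        }
      }
      size <- sizes$size[match(chrom, sizes$chrom)]
      if (strand == "+") {
        body_start <- tss; body_end <- min(size, tss + 2000L)
      } else {
        body_start <- max(0L, tss - 1999L); body_end <- tss + 1L
      }
      genes[[i]] <- tibble(gene_id = gid, chrom = chrom,
                           start = as.integer(body_start),
                           end = as.integer(body_end),
                           strand = strand, tss = as.integer(tss))
    }
    list(genes = bind_rows(genes), true_pairs = bind_rows(pairs))
  })
}

#' Simulate fragments and cell metadata
#'
#' Per-cell fragment left-insertion sites are drawn from a per-base
#' Poisson rate: a uniform genome-wide background plus, for each peak of
#' the cell's type, a mass split between a uniform in-peak component and
#' a Gaussian centred on the motif instance. Each drawn site `s` becomes
#' a fragment `[s - 4, s - 4 + len)` so that the +4-shifted start
#' insertion lands exactly at `s`. Cell metadata carries QC fields, with
#' `qc_fail_fraction` of cells violating exactly one QC threshold.
#'
#' @param genome Genome (used for chromosome sizes).
#' @param peaks,motif_instances From [plant_peaks_and_motifs()].
#' @param cfg A [synth_config()].
#' @return List with `fragments` (tibble `chrom,start,end,barcode,count`,
#'   attribute `n_draws` = internal draw count) and `cells` (QC metadata
#'   with `barcode`, `cell_type`, `donor`, `qc_fail`).
#' @export
simulate_fragments <- function(genome, peaks, motif_instances, cfg) {
  sizes <- chrom_sizes_of(genome)
  withr::with_seed(derive_seed(cfg$seed, "fragments"), {
    cells <- make_cells(cfg)
    frags <- vector("list", length(cfg$cell_types))
    for (t in seq_along(cfg$cell_types)) {
      ct <- cfg$cell_types[t]
      p <- peaks[peaks$cell_type == ct, , drop = FALSE]
      bc <- cells$barcode[cells$cell_type == ct]
      masses <- c(cfg$background_fragments_per_cell,
                  cfg$peak_fragments_per_cell * cfg$motif_strength * p$strength)
      lambda <- sum(masses)
      n_per_cell <- rpois(length(bc), lambda)
      n_tot <- sum(n_per_cell)
      if (n_tot == 0) {
        frags[[t]] <- tibble(chrom = character(), start = integer(),
                             end = integer(), barcode = character(),
                             count = integer())
        next
      }
      comp <- sample.int(length(masses), n_tot, replace = TRUE,
                         prob = masses)
      pos <- integer(n_tot)
      chrom <- character(n_tot)
      bg <- comp == 1L
      if (any(bg)) {
        ci <- sample.int(nrow(sizes), sum(bg), replace = TRUE,
                         prob = sizes$size)
        chrom[bg] <- sizes$chrom[ci]
        pos[bg] <- floor(runif(sum(bg)) * sizes$size[ci])
      }
      if (any(!bg)) {
        pk <- comp[!bg] - 1L
        centre_list <- map(seq_len(nrow(p)), function(i) {
          mi <- motif_instances[motif_instances$peak_id == p$peak_id[i] &
                                  motif_instances$kind == "intact", ]
          if (nrow(mi) > 0) floor((mi$start + mi$end) / 2)
          else floor((p$start[i] + p$end[i]) / 2)
        })
        # each motif-component fragment centres on one of the copies
        centres <- numeric(length(pk))
        for (u in unique(pk)) {
          sel <- which(pk == u)
          cl <- centre_list[[u]]
          centres[sel] <- cl[sample.int(length(cl), length(sel),
                                        replace = TRUE)]
        }
        at_motif <- runif(length(pk)) < cfg$motif_mass
        draw <- ifelse(at_motif,
                       round(rnorm(length(pk), centres, cfg$motif_sd)),
                       p$start[pk] + floor(runif(length(pk)) *
                                             (p$end[pk] - p$start[pk])))
        draw <- pmin(pmax(draw, p$start[pk]), p$end[pk] - 1L)
        pos[!bg] <- as.integer(draw)
        chrom[!bg] <- p$chrom[pk]
      }
      len <- sample(seq(cfg$frag_length_range[1], cfg$frag_length_range[2]),
                    n_tot, replace = TRUE)
      size_of <- sizes$size[match(chrom, sizes$chrom)]
      s <- pmin(pmax(pos, 4L), size_of - len + 3L)
      frags[[t]] <- tibble(chrom = chrom,
                           start = as.integer(s - 4L),
                           end = as.integer(s - 4L + len),
                           barcode = rep(bc, n_per_cell),
                           count = 1L)
    }
    fragments <- bind_rows(frags) |>
      arrange(.data$chrom, .data$start)
    attr(fragments, "n_draws") <- sum(fragments$count)
    list(fragments = fragments, cells = cells)
  })
}

# Cell metadata with QC fields; exactly one violated threshold per
# failing cell, drawn clear of every boundary it must respect.
make_cells <- function(cfg) {
  out <- vector("list", length(cfg$cell_types))
  for (t in seq_along(cfg$cell_types)) {
    ct <- cfg$cell_types[t]
    n <- cfg$n_cells_per_type
    donor <- rep(seq_len(cfg$n_donors), length.out = n)
    barcode <- sprintf("%s_d%d_c%04d", ct, donor, seq_len(n))
    cells <- tibble(
      barcode = barcode, cell_type = ct,
      donor = sprintf("donor%d", donor),
      n_transcripts = as.integer(round(runif(n, 1000, 20000))),
      pct_mito = runif(n, 0, 0.9),
      pct_ribo = runif(n, 0, 4.5),
      tss_enrichment = runif(n, 6.5, 15),
      n_fragments = as.integer(round(runif(n, 5000, 20000))),
      qc_fail = FALSE)
    n_fail <- round(cfg$qc_fail_fraction * n)
    if (n_fail > 0) {
      fail_idx <- sample.int(n, n_fail)
      metric <- sample(c("transcripts_low", "transcripts_high", "mito",
                         "ribo", "tss", "fragments"),
                       n_fail, replace = TRUE)
      for (k in seq_len(n_fail)) {
        i <- fail_idx[k]
        switch(metric[k],
          transcripts_low = { cells$n_transcripts[i] <- sample(0:199, 1) },
          transcripts_high = { cells$n_transcripts[i] <-
            as.integer(round(runif(1, 50001, 80000))) },
          mito = { cells$pct_mito[i] <- runif(1, 1.001, 5) },
          ribo = { cells$pct_ribo[i] <- runif(1, 5.001, 15) },
          tss = { cells$tss_enrichment[i] <- runif(1, 1, 6) },
          fragments = { cells$n_fragments[i] <- sample(0:2500, 1) })
        cells$qc_fail[i] <- TRUE
      }
    }
    out[[t]] <- cells
  }
  bind_rows(out)
}

#' Simulate expression linked to peak accessibility
#'
#' Linked genes' per-cell expected expression is an affine function of
#' the cell's insertion count in the linked peak
#' (`expr_intercept + expr_slope * count`), with Poisson noise (or none);
#' unlinked genes are independent Poisson draws at `expr_base`.
#'
#' @param fragments,cells From [simulate_fragments()].
#' @param peaks Peak tibble.
#' @param genes Gene tibble (every gene must carry a `tss`).
#' @param true_pairs Tibble `peak_id`, `gene_id` of linked pairs.
#' @param cfg A [synth_config()].
#' @return Integer matrix genes x cells (dimnames gene_id, barcode).
#' @export
simulate_expression <- function(fragments, cells, peaks, genes,
                                true_pairs, cfg) {
  assert_cols(genes, c("gene_id", "tss"))
  if (any(is.na(genes$tss))) abort("simulate_expression: gene without TSS")
  withr::with_seed(derive_seed(cfg$seed, "expression"), {
    expr <- matrix(0L, nrow = nrow(genes), ncol = nrow(cells),
                   dimnames = list(genes$gene_id, cells$barcode))
    unlinked <- setdiff(genes$gene_id, true_pairs$gene_id)
    if (length(unlinked) > 0) {
      expr[unlinked, ] <- matrix(
        rpois(length(unlinked) * nrow(cells), cfg$expr_base),
        nrow = length(unlinked))
    }
    if (nrow(true_pairs) > 0) {
      pk <- peaks[match(true_pairs$peak_id, peaks$peak_id), ]
      acc <- peak_cell_counts(fragments, pk, cells$barcode)
      for (i in seq_len(nrow(true_pairs))) {
        mu <- cfg$expr_intercept + cfg$expr_slope * acc[i, ]
        expr[true_pairs$gene_id[i], ] <-
          if (cfg$expr_noise == "poisson") rpois(length(mu), pmax(mu, 0))
          else as.integer(round(pmax(mu, 0)))
      }
    }
    expr
  })
}

#' Per-cell insertion counts in peaks
#'
#' Counts +4/-4-shifted insertion events (two per fragment) falling in
#' each peak, per barcode.
#'
#' @param fragments Fragment tibble.
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param barcodes Barcodes defining the column order.
#' @return Numeric matrix `nrow(peaks)` x `length(barcodes)`.
#' @export
peak_cell_counts <- function(fragments, peaks, barcodes) {
  m <- matrix(0, nrow = nrow(peaks), ncol = length(barcodes),
              dimnames = list(peaks$peak_id %||% NULL, barcodes))
  if (nrow(fragments) == 0 || nrow(peaks) == 0) return(m)
  pts <- tibble(
    chrom = rep(fragments$chrom, 2),
    start = c(fragments$start + 4L, fragments$end - 5L),
    barcode = rep(fragments$barcode, 2),
    count = rep(fragments$count, 2))
  pts$end <- pts$start + 1L
  hits <- intersect_any(pts, peaks)
  if (nrow(hits) == 0) return(m)
  bi <- match(pts$barcode[hits$idx_a], barcodes)
  keep <- !is.na(bi)
  if (!any(keep)) return(m)
  agg <- rowsum(pts$count[hits$idx_a][keep],
                (hits$idx_b[keep] - 1L) * length(barcodes) + bi[keep])
  flat <- as.integer(rownames(agg))
  m[cbind(((flat - 1L) %/% length(barcodes)) + 1L,
          ((flat - 1L) %% length(barcodes)) + 1L)] <- agg[, 1]
  m
}

#' Simulate SNP tables, loops and eQTL summaries
#'
#' Index SNPs get LD blocks of proxies with R^2 > 0.9; a configured
#' fraction of blocks carry a planted effect SNP (motif-disrupting: alt
#' is the lowest-probability base at the most informative position of an
#' intact in-peak instance; or motif-creating: alt restores a broken
#' background instance). Loops connect a fraction of true peak-gene
#' pairs with 5 kb anchors; eQTL rows carry small nominal p (Beta(1,5000))
#' for true SNP-gene pairs and Uniform(0,1) otherwise.
#'
#' @param genome Genome with motifs written in.
#' @param peaks,motif_instances From [plant_peaks_and_motifs()].
#' @param genes,true_pairs From the gene-placement step.
#' @param cfg A [synth_config()].
#' @return List with `snps`, `loops`, `eqtl`, `truth` (list of
#'   `true_peak_gene_pairs`, `true_high_effect_snps`, `true_loops`,
#'   `true_eqtl_pairs`).
#' @export
simulate_snps_loops_eqtl <- function(genome, peaks, motif_instances,
                                     genes, true_pairs, cfg) {
  sizes <- chrom_sizes_of(genome)
  n_effect <- round(cfg$effect_snp_fraction * cfg$n_index_snps)
  n_gain <- round(cfg$gain_fraction * n_effect)
  n_loss <- n_effect - n_gain
  intact <- motif_instances[motif_instances$kind == "intact", ]
  broken <- motif_instances[motif_instances$kind == "broken_background", ]
  if (n_loss > nrow(intact)) {
    abort("effect_snp_fraction requires more motif-disrupting sites than planted motif instances")
  }
  if (n_gain > nrow(broken)) {
    abort("gain_fraction requires more broken background instances than planted")
  }
  base_at <- function(chrom, pos0) {
    as.character(Biostrings::extractAt(
      genome[[chrom]], IRanges::IRanges(pos0 + 1L, width = 1L)))
  }
  withr::with_seed(derive_seed(cfg$seed, "snps"), {
    # loss sites live in single-copy peaks (the SNP removes the peak's
    # only motif instance); prefer peaks that carry a true gene link
    single <- peaks$peak_id[peaks$n_copies == 1]
    intact <- intact[intact$peak_id %in% single, , drop = FALSE]
    pref <- order(!(intact$peak_id %in% true_pairs$peak_id))
    # one instance per distinct peak
    pref <- pref[!duplicated(intact$peak_id[pref])]
    if (n_loss > length(pref)) {
      abort("effect_snp_fraction requires more distinct peaks than available")
    }
    loss_sites <- intact[pref[seq_len(n_loss)], , drop = FALSE]
    gain_sites <- if (n_gain > 0) broken[seq_len(n_gain), , drop = FALSE]
                  else broken[0, ]

    effect <- vector("list", n_effect)
    k <- 0
    for (i in seq_len(nrow(loss_sites))) {
      k <- k + 1
      pwm <- cfg$motifs[[loss_sites$motif[i]]]
      j <- pwm_max_info_position(pwm)
      pos <- loss_sites$start[i] + j - 1L
      ref <- base_at(loss_sites$chrom[i], pos)
      effect[[k]] <- tibble(chrom = loss_sites$chrom[i], pos = pos,
                            ref = ref, alt = pwm_worst_base(pwm, j),
                            direction = "loss")
    }
    for (i in seq_len(nrow(gain_sites))) {
      k <- k + 1
      pwm <- cfg$motifs[[gain_sites$motif[i]]]
      j <- pwm_max_info_position(pwm)
      pos <- gain_sites$start[i] + j - 1L
      ref <- base_at(gain_sites$chrom[i], pos)
      cons <- substr(attr(pwm, "consensus"), j, j)
      effect[[k]] <- tibble(chrom = gain_sites$chrom[i], pos = pos,
                            ref = ref, alt = cons, direction = "gain")
    }
    effect <- bind_rows(effect)

    in_any_peak <- function(chrom, pos) {
      any(peaks$chrom == chrom & peaks$start <= pos & peaks$end > pos)
    }
    random_neutral <- function(near_chrom = NULL, near_pos = NULL) {
      repeat {
        if (is.null(near_chrom)) {
          ci <- sample.int(nrow(sizes), 1, prob = sizes$size)
          chrom <- sizes$chrom[ci]
          pos <- 2000L + sample.int(sizes$size[ci] - 4000L, 1)
        } else {
          chrom <- near_chrom
          size <- sizes$size[match(chrom, sizes$chrom)]
          pos <- min(max(near_pos + sample(seq(-40000L, 40000L), 1), 2000L),
                     size - 2000L)
        }
        if (!in_any_peak(chrom, pos)) {
          ref <- base_at(chrom, pos)
          if (ref %in% c("A", "C", "G", "T")) {
            return(tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                          alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1)))
          }
        }
      }
    }

    # LD blocks: one index SNP + ld_block_size proxies each; the first
    # n_effect blocks carry an effect SNP as one of their proxies
    rows <- list()
    rs <- 0
    next_rsid <- function() { rs <<- rs + 1; sprintf("rs%06d", rs) }
    truth_effect <- tibble(rsid = character(), direction = character())
    for (b in seq_len(cfg$n_index_snps)) {
      disease <- cfg$diseases[((b - 1) %% length(cfg$diseases)) + 1]
      has_effect <- b <= n_effect
      anchor <- if (has_effect) {
        list(chrom = effect$chrom[b], pos = effect$pos[b])
      } else {
        nt <- random_neutral()
        list(chrom = nt$chrom, pos = nt$pos)
      }
      idx <- random_neutral(anchor$chrom, anchor$pos)
      rows[[length(rows) + 1]] <- mutate(idx, rsid = next_rsid(),
                                         disease = disease,
                                         snp_set = "index", r2 = NA_real_,
                                         coding = FALSE)
      n_proxy <- cfg$ld_block_size
      for (p in seq_len(n_proxy)) {
        if (has_effect && p == 1) {
          snp <- effect[b, c("chrom", "pos", "ref", "alt")]
          rid <- next_rsid()
          truth_effect <- bind_rows(truth_effect,
                                    tibble(rsid = rid,
                                           direction = effect$direction[b]))
        } else {
          snp <- random_neutral(anchor$chrom, anchor$pos)
          rid <- next_rsid()
        }
        rows[[length(rows) + 1]] <- mutate(snp, rsid = rid,
                                           disease = disease,
                                           snp_set = "ld_expanded",
                                           r2 = runif(1, 0.901, 0.999),
                                           coding = FALSE)
      }
    }
    snps <- bind_rows(rows)

    # coding SNPs inside gene bodies (exercise the coding filter)
    n_coding <- round(cfg$coding_fraction * nrow(snps))
    if (n_coding > 0 && nrow(genes) > 0) {
      for (i in seq_len(n_coding)) {
        g <- genes[sample.int(nrow(genes), 1), ]
        pos <- g$start + sample.int(g$end - g$start, 1) - 1L
        ref <- base_at(g$chrom, pos)
        snps <- bind_rows(snps, tibble(
          chrom = g$chrom, pos = as.integer(pos), ref = ref,
          alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
          rsid = next_rsid(),
          disease = cfg$diseases[((i - 1) %% length(cfg$diseases)) + 1],
          snp_set = "ld_expanded", r2 = runif(1, 0.901, 0.999),
          coding = TRUE))
      }
    }

    # neutral background universe for background-set construction
    if (cfg$n_background_snps > 0) {
      bg <- map(seq_len(cfg$n_background_snps), ~ random_neutral())
      bg <- bind_rows(bg) |>
        mutate(rsid = vapply(seq_len(cfg$n_background_snps),
                             function(i) next_rsid(), character(1)),
               disease = NA_character_, snp_set = "background",
               r2 = NA_real_,
               coding = runif(cfg$n_background_snps) < cfg$coding_fraction)
      snps <- bind_rows(snps, bg)
    }
    snps <- select(snps, "chrom", "pos", "rsid", "ref", "alt", "disease",
                   "snp_set", "r2", "coding")

    # loops over a fraction of true peak-gene pairs (5 kb anchors)
    n_loop <- round(cfg$loop_fraction * nrow(true_pairs))
    loop_pairs <- true_pairs[sample.int(nrow(true_pairs),
                                        min(n_loop, nrow(true_pairs))), ]
    loops <- tibble(chrom1 = character(), start1 = integer(),
                    end1 = integer(), chrom2 = character(),
                    start2 = integer(), end2 = integer(),
                    peak_id = character(), gene_id = character())
    if (nrow(loop_pairs) > 0) {
      pk <- peaks[match(loop_pairs$peak_id, peaks$peak_id), ]
      gn <- genes[match(loop_pairs$gene_id, genes$gene_id), ]
      centre <- floor((pk$start + pk$end) / 2)
      loops <- tibble(
        chrom1 = pk$chrom,
        start1 = as.integer(pmax(0, centre - 2500L)),
        end1 = as.integer(centre + 2500L),
        chrom2 = gn$chrom,
        start2 = as.integer(pmax(0, gn$tss - 2500L)),
        end2 = as.integer(gn$tss + 2500L),
        peak_id = loop_pairs$peak_id, gene_id = loop_pairs$gene_id)
    }

    # eQTL summary rows: candidate genes within 250 kb of each disease SNP
    disease_snps <- snps[snps$snp_set %in% c("index", "ld_expanded") &
                           !snps$coding, ]
    true_eqtl <- tibble(rsid = character(), gene_id = character())
    eqtl_rows <- list()
    snp_peak <- snp_in_peaks(disease_snps, peaks)
    for (i in seq_len(nrow(disease_snps))) {
      s <- disease_snps[i, ]
      cand <- genes[genes$chrom == s$chrom &
                      abs(genes$tss - s$pos) <= 250000, ]
      if (nrow(cand) == 0) next
      peaks_of_snp <- peaks$peak_id[snp_peak$peak_idx[snp_peak$rsid == s$rsid]]
      linked_genes <- true_pairs$gene_id[true_pairs$peak_id %in% peaks_of_snp]
      is_true <- cand$gene_id %in% linked_genes
      p <- ifelse(is_true, rbeta(nrow(cand), 1, 5000), runif(nrow(cand)))
      eqtl_rows[[length(eqtl_rows) + 1]] <- tibble(
        rsid = s$rsid, gene_id = cand$gene_id, nominal_p = p,
        n_pairs = nrow(cand))
      if (any(is_true)) {
        true_eqtl <- bind_rows(true_eqtl,
                               tibble(rsid = s$rsid,
                                      gene_id = cand$gene_id[is_true]))
      }
    }
    eqtl <- bind_rows(eqtl_rows)

    truth <- list(true_peak_gene_pairs = true_pairs,
                  true_high_effect_snps = truth_effect,
                  true_loops = loops[c("peak_id", "gene_id")],
                  true_eqtl_pairs = true_eqtl)
    list(snps = snps, loops = loops[, 1:6], truth = truth, eqtl = eqtl)
  })
}

#' Generate a complete synthetic multiome
#'
#' Chains genome generation, peak/motif planting, gene placement,
#' fragment simulation, expression simulation and SNP/loop/eQTL
#' simulation. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A `synth_multiome` list: `config`, `genome`, `chrom_sizes`,
#'   `peaks`, `replicate_peaks`, `motif_instances`, `genes`, `cells`,
#'   `fragments`, `expression`, `snps`, `loops`, `eqtl`, `truth`.
#' @export
synth_multiome <- function(cfg = synth_config()) {
  genome <- generate_genome(cfg)
  planted <- plant_peaks_and_motifs(genome, cfg)
  sizes <- chrom_sizes_of(planted$genome)
  gn <- place_genes(planted$peaks, sizes, cfg)
  fr <- simulate_fragments(planted$genome, planted$peaks,
                           planted$motif_instances, cfg)
  expr <- simulate_expression(fr$fragments, fr$cells, planted$peaks,
                              gn$genes, gn$true_pairs, cfg)
  sv <- simulate_snps_loops_eqtl(planted$genome, planted$peaks,
                                 planted$motif_instances, gn$genes,
                                 gn$true_pairs, cfg)
  structure(list(config = cfg, genome = planted$genome,
                 chrom_sizes = sizes, peaks = planted$peaks,
                 replicate_peaks = planted$replicate_peaks,
                 motif_instances = planted$motif_instances,
                 genes = gn$genes, cells = fr$cells,
                 fragments = fr$fragments, expression = expr,
                 snps = sv$snps, loops = sv$loops, eqtl = sv$eqtl,
                 truth = sv$truth),
            class = "synth_multiome")
}

#' @export
print.synth_multiome <- function(x, ...) {
  cat(sprintf(
    "<synth_multiome> %d chrom(s) x %g bp | %d cells (%d types) | %d peak calls | %d genes | %d SNPs | %d loops\n",
    nrow(x$chrom_sizes), x$chrom_sizes$size[1], nrow(x$cells),
    length(x$config$cell_types), nrow(x$peaks), nrow(x$genes),
    nrow(x$snps), nrow(x$loops)))
  invisible(x)
}

#' Write a synthetic multiome to standard file formats
#'
#' FASTA genome, chrom.sizes, fragments TSV, per-replicate peak BED
#' files, loops BEDPE, SNP/eQTL/cell/gene TSVs, dense expression TSV and
#' a ground-truth JSON.
#'
#' @param mo A `synth_multiome`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_multiome <- function(mo, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  Biostrings::writeXStringSet(mo$genome, fp("genome.fa"))
  readr::write_tsv(mo$chrom_sizes, fp("chrom.sizes"), col_names = FALSE)
  write_fragments(mo$fragments, fp("fragments.tsv"))
  for (ct in unique(mo$replicate_peaks$cell_type)) {
    for (rep in unique(mo$replicate_peaks$replicate)) {
      sub <- filter(mo$replicate_peaks, .data$cell_type == ct,
                    .data$replicate == rep)
      write_bed(mutate(sub, name = .data$peak_id),
                fp(sprintf("peaks_%s_%s.bed", ct, rep)))
    }
  }
  write_bedpe(mo$loops, fp("loops.bedpe"))
  write_snp_table(mo$snps, fp("snps.tsv"))
  write_eqtl(mo$eqtl, fp("eqtl.tsv"))
  readr::write_tsv(mo$cells, fp("cells.tsv"))
  readr::write_tsv(mo$genes, fp("genes.tsv"))
  expr <- as_tibble(mo$expression, rownames = "gene_id")
  readr::write_tsv(expr, fp("expression.tsv"))
  jsonlite::write_json(
    list(true_peak_gene_pairs = mo$truth$true_peak_gene_pairs,
         true_high_effect_snps = mo$truth$true_high_effect_snps,
         true_loops = mo$truth$true_loops,
         true_eqtl_pairs = mo$truth$true_eqtl_pairs),
    fp("ground_truth.json"), dataframe = "rows")
  invisible(dir)
}
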