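test_that("promoter windows are strand-aware and match brute force", {
  genes <- tibble::tibble(gene_id = c("gP", "gM"), chrom = "chr1",
                          tss = c(10000L, 30000L), strand = c("+", "-"))
  # peak at [tss-500, tss-400) of the + strand gene: inside upstream window
  p1 <- tibble::tibble(chrom = "chr1", start = 9500L, end = 9600L)
  expect_true(promoter_peaks(p1, genes[1, ])$is_promoter)
  # same offset relative to a - strand gene: outside [tss-100, tss+2000)
  p2 <- tibble::tibble(chrom = "chr1", start = 29500L, end = 29600L)
  expect_false(promoter_peaks(p2, genes[2, ])$is_promoter)
  # downstream of a - strand TSS means smaller coordinates
  p3 <- tibble::tibble(chrom = "chr1", start = 30050L, end = 30150L)
  expect_true(promoter_peaks(p3, genes[2, ])$is_promoter)

  mo <- tiny_mo()
  got <- promoter_peaks(mo$peaks, mo$genes)
  win <- tibble::tibble(
    chrom = mo$genes$chrom,
    start = ifelse(mo$genes$strand == "+", mo$genes$tss - 2000L,
                   mo$genes$tss - 100L),
    end = ifelse(mo$genes$strand == "+", mo$genes$tss + 100L,
                 mo$genes$tss + 2000L))
  want <- brute_overlaps(mo$peaks, win)
  expect_setequal(which(got$is_promoter), unique(want$idx_a))
})

test_that("cell aggregation is identity-like and permutation-invariant", {
  acc <- matrix(c(10, 0, 5, 20, 0, 5), nrow = 2,
                dimnames = list(c("p1", "p2"), c("c1", "c2", "c3")))
  expr <- matrix(c(4, 1, 2, 8, 1, 2), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  groups <- tibble::tibble(barcode = c("c1", "c2", "c3"),
                           group = c("a", "b", "c"))
  agg <- aggregate_cells(acc, expr, groups)
  # identity groups: depth-normalized columns of the input
  expect_equal(agg$acc[, "a"], acc[, "c1"] / sum(acc[, "c1"]) * 1e4)
  expect_equal(agg$expr[, "a"],
               log1p(expr[, "c1"] / sum(expr[, "c1"]) * 1e4))
  # permuting cells within groups leaves output unchanged
  g2 <- tibble::tibble(barcode = c("c3", "c1", "c2"),
                       group = c("a", "a", "b"))
  g2p <- g2[c(2, 1, 3), ]
  a1 <- suppressWarnings(aggregate_cells(acc, expr, dplyr::bind_rows(
    g2, tibble::tibble(barcode = "c2", group = "c"))))
  a2 <- suppressWarnings(aggregate_cells(acc, expr, dplyr::bind_rows(
    g2p, tibble::tibble(barcode = "c2", group = "c"))))
  expect_equal(a1, a2)
  expect_error(aggregate_cells(acc, expr, groups[1:2, ]), ">= 3 aggregates")
})

test_that("co-accessibility computes textbook Pearson r with a strict cutoff", {
  peaks <- tibble::tibble(peak_id = c("p1", "p2", "p3"), chrom = "chr1",
                          start = c(0L, 10000L, 20000L),
                          end = c(500L, 10500L, 20500L))
  acc <- rbind(p1 = c(1, 2, 3), p2 = c(1, 2, 3), p3 = c(3, 2, 1))
  links <- coaccessibility(acc, peaks)
  # identical vectors -> r = 1, linked; anti-correlated pair is not
  expect_equal(nrow(links), 1)
  expect_equal(links$peak1, "p1")
  expect_equal(links$peak2, "p2")
  expect_equal(links$r, 1)
  # r matches the direct formula on a hand-computable 3-point toy
  expect_equal(links$r, stats::cor(c(1, 2, 3), c(1, 2, 3)))
  # distance bound excludes far pairs
  far <- peaks
  far$start[2] <- 400000L; far$end[2] <- 400500L
  expect_equal(nrow(coaccessibility(acc, far)), 0)
  # zero-variance peaks are skipped and counted
  acc0 <- rbind(p1 = c(1, 2, 3), p2 = c(2, 2, 2), p3 = c(1, 2, 3))
  l0 <- coaccessibility(acc0, peaks)
  expect_equal(attr(l0, "n_skipped_zero_var"), 2L)
})

test_that("null co-accessibility link rate matches a permutation null", {
  withr::with_seed(31, {
    n_peaks <- 40; n_agg <- 50
    acc <- matrix(rnorm(n_peaks * n_agg), n_peaks,
                  dimnames = list(sprintf("p%02d", 1:n_peaks), NULL))
    peaks <- tibble::tibble(peak_id = rownames(acc), chrom = "chr1",
                            start = seq(0L, by = 2000L, length.out = n_peaks))
    peaks$end <- peaks$start + 500L
    links <- coaccessibility(acc, peaks)
    n_pairs <- choose(n_peaks, 2)
    observed_rate <- nrow(links) / n_pairs
    # permutation null: shuffle aggregate labels independently per peak
    null_rates <- replicate(20, {
      perm <- t(apply(acc, 1, sample))
      rownames(perm) <- rownames(acc)
      nrow(coaccessibility(perm, peaks)) / n_pairs
    })
    expect_lt(abs(observed_rate - mean(null_rates)),
              4 * stats::sd(null_rates) + 0.02)
  })
})

test_that("peak2gene links accessibility to expression with nearest-gene flag", {
  peaks <- tibble::tibble(peak_id = c("p1", "p2"), chrom = "chr1",
                          start = c(1000L, 50000L), end = c(1500L, 50500L))
  genes <- tibble::tibble(gene_id = c("gNear", "gFar"), chrom = "chr1",
                          start = c(2000L, 90000L), end = c(4000L, 92000L),
                          tss = c(2000L, 90000L))
  acc <- rbind(p1 = c(5, 1, 0, 2), p2 = c(0, 4, 4, 0))
  expr <- rbind(gNear = c(0, 8, 8, 0), gFar = c(10, 2, 0, 4))
  links <- peak2gene(acc, expr, peaks, genes, max_distance = 2e5)
  # p1 correlates with gFar (not its nearest gene), p2 with gNear
  expect_setequal(paste(links$peak_id, links$gene_id),
                  c("p1 gFar", "p2 gNear"))
  expect_true(all(links$r > 0.3))
  expect_true(links$differs_from_nearest[links$peak_id == "p1"])
  # cutoff 1.0 can never be exceeded (strict >) -> no links
  expect_equal(nrow(peak2gene(acc, expr, peaks, genes, cutoff = 1,
                              max_distance = 2e5)), 0)
})

test_that("generator's linked pairs are recovered at high sensitivity", {
  mo <- tiny_mo()
  kept <- qc_filter_cells(mo$cells)
  frags <- mo$fragments[mo$fragments$barcode %in% kept$barcode, ]
  peaks <- dplyr::distinct(mo$peaks, peak_id, chrom, start, end)
  acc <- peak_cell_counts(frags, peaks, kept$barcode)
  groups <- tibble::tibble(barcode = kept$barcode,
                           group = paste(kept$cell_type, kept$donor))
  agg <- aggregate_cells(acc, mo$expression[, kept$barcode], groups)
  links <- peak2gene(agg$acc, agg$expr, peaks, mo$genes)
  truth <- mo$truth$true_peak_gene_pairs
  hit <- mapply(function(p, g) any(links$peak_id == p & links$gene_id == g),
                truth$peak_id, truth$gene_id)
  expect_gte(mean(hit), 0.9)

  # planted slope 0: true pairs recovered at no more than the chance rate
  cfg0 <- tiny_config(seed = 101, expr_slope = 0)
  mo0 <- suppressWarnings(synth_multiome(cfg0))
  kept0 <- qc_filter_cells(mo0$cells)
  fr0 <- mo0$fragments[mo0$fragments$barcode %in% kept0$barcode, ]
  pk0 <- dplyr::distinct(mo0$peaks, peak_id, chrom, start, end)
  acc0 <- peak_cell_counts(fr0, pk0, kept0$barcode)
  agg0 <- aggregate_cells(acc0, mo0$expression[, kept0$barcode],
                          tibble::tibble(barcode = kept0$barcode,
                                         group = paste(kept0$cell_type,
                                                       kept0$donor)))
  links0 <- peak2gene(agg0$acc, agg0$expr, pk0, mo0$genes)
  truth0 <- mo0$truth$true_peak_gene_pairs
  hit0 <- mapply(function(p, g) any(links0$peak_id == p & links0$gene_id == g),
                 truth0$peak_id, truth0$gene_id)
  # chance rate for r > 0.3 with 8 aggregates is well under one half;
  # recovery must collapse relative to the planted-slope case
  expect_lt(mean(hit0), 0.5)
})

test_that("loop links require SNP peak in one anchor and TSS in the other", {
  peaks <- tibble::tibble(peak_id = "p1", chrom = "chr1", start = 1000L,
                          end = 1400L, cell_type = "rod")
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          tss = c(52000L, 1100L))
  loops <- tibble::tibble(chrom1 = "chr1", start1 = 0L, end1 = 5000L,
                          chrom2 = "chr1", start2 = 50000L, end2 = 55000L)
  snps <- tibble::tibble(chrom = "chr1", pos = 1200L, rsid = "rs1")
  got <- loop_gene_links(snps, peaks, loops, genes)
  # SNP's peak overlaps anchor1, gA's TSS in anchor2 -> linked;
  # gB's TSS shares anchor1 with the SNP -> not linked
  expect_equal(got, tibble::tibble(rsid = "rs1", gene_id = "gA"))
  # SNP outside every peak -> nothing
  out <- loop_gene_links(dplyr::mutate(snps, pos = 20000L), peaks, loops,
                         genes)
  expect_equal(nrow(out), 0)
})

test_that("loop link counts match brute force on the synthetic fixture", {
  mo <- tiny_mo()
  snps <- mo$snps[mo$snps$snp_set %in% c("index", "ld_expanded"), ]
  # guarantee at least one positive case: a SNP in the centre of a
  # looped peak
  looped <- mo$peaks[match(mo$truth$true_loops$peak_id, mo$peaks$peak_id), ]
  centre <- floor((looped$start[1] + looped$end[1]) / 2)
  extra <- tibble::tibble(chrom = looped$chrom[1], pos = centre,
                          rsid = "rs_in_loop", ref = "A", alt = "G",
                          disease = "AMD", snp_set = "ld_expanded",
                          r2 = 0.95, coding = FALSE)
  snps <- dplyr::bind_rows(snps[names(extra)], extra)
  got <- loop_gene_links(snps, mo$peaks, mo$loops, mo$genes)
  expect_true("rs_in_loop" %in% got$rsid)
  # brute force
  want <- list()
  for (i in seq_len(nrow(snps))) {
    pk <- mo$peaks[mo$peaks$chrom == snps$chrom[i] &
                     mo$peaks$start <= snps$pos[i] &
                     mo$peaks$end > snps$pos[i], ]
    if (nrow(pk) == 0) next
    for (l in seq_len(nrow(mo$loops))) {
      lp <- mo$loops[l, ]
      pk_in_1 <- any(pk$chrom == lp$chrom1 & pk$start < lp$end1 &
                       lp$start1 < pk$end)
      pk_in_2 <- any(pk$chrom == lp$chrom2 & pk$start < lp$end2 &
                       lp$start2 < pk$end)
      for (g in seq_len(nrow(mo$genes))) {
        gn <- mo$genes[g, ]
        tss_in_1 <- gn$chrom == lp$chrom1 & gn$tss >= lp$start1 &
          gn$tss < lp$end1
        tss_in_2 <- gn$chrom == lp$chrom2 & gn$tss >= lp$start2 &
          gn$tss < lp$end2
        if ((pk_in_1 && tss_in_2) || (pk_in_2 && tss_in_1)) {
          want[[length(want) + 1]] <- paste(snps$rsid[i], gn$gene_id)
        }
      }
    }
  }
  want_v <- if (length(want) > 0) unique(unlist(want)) else character(0)
  expect_setequal(paste(got$rsid, got$gene_id), want_v)
})
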