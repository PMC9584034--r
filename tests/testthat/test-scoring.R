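test_that("the one-sided Poisson test matches direct tail evaluation", {
  # alt = ref = 5: k = 5, p = P(X >= 5 | lambda = 5)
  expect_equal(poisson_allele_test(5, 5),
               1 - ppois(4, 5), tolerance = 1e-12)
  expect_equal(round(poisson_allele_test(5, 5), 4), 0.5595)
  # tail monotonicity: p -> 0 as alt grows at fixed ref
  ps <- poisson_allele_test(c(5, 10, 20, 40, 80), 5)
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[5], 1e-10)
  # lower tail when alt < ref
  expect_equal(poisson_allele_test(2, 10), ppois(2, 10), tolerance = 1e-12)
  expect_error(poisson_allele_test(3, 0), "ref count must be > 0")
  # p always in (0, 1]
  expect_equal(poisson_allele_test(0.2, 0.1), 1)  # k = 0, upper tail
})

test_that("Poisson tails agree with brute-force pmf summation", {
  for (lambda in c(0.5, 1, 2, 5, 10, 20)) {
    for (k in c(0:10, 20, 40, 60)) {
      brute_upper <- sum(dpois(k:400, lambda))
      brute_lower <- sum(dpois(0:k, lambda))
      expect_equal(poisson_allele_test(k, lambda, direction = "upper"),
                   min(1, brute_upper), tolerance = 1e-10)
      if (k < lambda) {
        expect_equal(poisson_allele_test(k, lambda), brute_lower,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("the continuous-tail option interpolates the discrete test", {
  # at integer alt, the gamma continuation equals the discrete upper tail
  expect_equal(poisson_allele_test(7, 4, rounding = "continuous"),
               poisson_allele_test(7, 4, direction = "upper"),
               tolerance = 1e-12)
  # and is monotone in alt between integers
  p <- poisson_allele_test(c(6, 6.5, 7), 4, rounding = "continuous",
                           direction = "upper")
  expect_true(all(diff(p) < 0))
})

test_that("Fisher combination matches an independent gamma-tail oracle", {
  expect_equal(fisher_combine(0.037), 0.037, tolerance = 1e-12)  # k = 1
  expect_equal(fisher_combine(rep(1, 6)), 1)
  withr::with_seed(59, {
    for (i in 1:100) {
      p <- runif(sample(2:8, 1))
      # -sum(log p) ~ Gamma(k, 1) under the null
      oracle <- pgamma(-sum(log(p)), shape = length(p), lower.tail = FALSE)
      expect_equal(fisher_combine(p), oracle, tolerance = 1e-10)
    }
  })
  # clamping of tiny p-values keeps the statistic finite
  expect_true(is.finite(fisher_combine(c(1e-320, 0.5))))
  expect_error(fisher_combine(numeric(0)), "empty")
})

test_that("BH adjustment matches the reference implementation", {
  expect_equal(bh_adjust(0.03), 0.03)
  # hand-computed step-up: p = (0.01, 0.02, 0.03, 0.04), m = 4 -> all 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(61, {
    for (i in 1:50) {
      p <- runif(sample(1:40, 1))
      expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    }
    # permutation equivariance
    p <- runif(20)
    perm <- sample(20)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  })
})

test_that("high-effect calls use strict thresholds on FDR and |log2FC|", {
  mk <- function(lfc, p) {
    tibble::tibble(rsid = sprintf("rs%02d", seq_along(lfc)),
                   cell_type = "rod", pred_ref = 100,
                   pred_alt = 100 * 2^lfc, mean_log2fc = lfc, poisson_p = p)
  }
  # |lfc| = 0.5 exactly -> never high-effect (strict >)
  v <- call_high_effect(mk(c(0.5, -0.5), c(1e-10, 1e-10)))
  expect_false(any(v$high_effect))
  # fdr exactly at threshold -> not high-effect
  cs <- mk(c(2, 2), c(0.5, 0.5))
  v2 <- call_high_effect(cs, scoring_config(fdr_threshold = 0.01))
  v2$fdr <- c(0.01, 0.009)
  flag <- v2$fdr < 0.01 & v2$max_abs_log2fc > 0.5
  expect_equal(flag, c(FALSE, TRUE))
  # a clear case is flagged
  v3 <- call_high_effect(mk(c(2, 0, 0, 0, 0), c(1e-12, .5, .6, .4, .5)))
  expect_equal(v3$high_effect, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("identical-prediction null yields zero log2FC and no calls", {
  # equal integer predicted counts for every SNP and cell type
  withr::with_seed(67, {
    lam <- sample(5:200, 40, replace = TRUE)
  })
  cs <- tibble::tibble(rsid = rep(sprintf("rs%02d", 1:10), each = 4),
                       cell_type = rep(c("a", "b", "c", "d"), 10),
                       pred_ref = as.numeric(lam), pred_alt = as.numeric(lam),
                       mean_log2fc = 0,
                       poisson_p = poisson_allele_test(lam, lam))
  # integer-valued counts: P(X >= lambda | lambda) >= 1/2 exactly
  expect_true(all(cs$poisson_p >= 0.5))
  v <- call_high_effect(cs)
  expect_equal(sum(v$high_effect), 0)
  expect_true(all(v$fdr > 0.05))
})

test_that("fixed upper-tail Poisson test is valid under the simulated null", {
  # alt ~ Poisson(ref): rejection rate at alpha = 0.05 must not exceed
  # alpha (the discrete test is conservative; exact rate checked too)
  alpha <- 0.05
  n_rep <- 10000
  for (lambda in c(20, 100, 400)) {
    withr::with_seed(71 + lambda, {
      alt <- rpois(n_rep, lambda)
    })
    p <- poisson_allele_test(alt, lambda, direction = "upper")
    rate <- mean(p <= alpha)
    se <- sqrt(alpha * (1 - alpha) / n_rep)
    expect_lte(rate, alpha + 3 * se)
    # empirical rate agrees with the analytic rejection probability
    k_crit <- qpois(1 - alpha, lambda) + 1
    while (poisson_allele_test(k_crit - 1, lambda, direction = "upper") <= alpha) {
      k_crit <- k_crit - 1
    }
    exact <- ppois(k_crit - 1, lambda, lower.tail = FALSE)
    expect_lt(abs(rate - exact), 4 * sqrt(exact * (1 - exact) / n_rep))
  }
})

test_that("background SNP construction shuffles, filters and truncates in order", {
  withr::with_seed(73, {
    universe <- tibble::tibble(
      chrom = sample(c("chr1", "chr2", "chrY"), 12000, TRUE),
      pos = sample.int(1e6, 12000, TRUE),
      rsid = sprintf("rs%05d", 1:12000),
      coding = FALSE)
  })
  got <- background_snps(universe, n = 10000, seed = 1,
                         allowed_chroms = c("chr1", "chr2"))
  # coding-free universe: exactly n taken, then chrY rows drop out
  expect_lt(nrow(got), 10000)
  expect_true(all(got$chrom %in% c("chr1", "chr2")))
  expect_equal(background_snps(universe, n = 10000, seed = 1,
                               allowed_chroms = c("chr1", "chr2")), got)
  # no chromosome filter: exactly n retained
  expect_equal(nrow(background_snps(universe, n = 10000, seed = 2)), 10000)
  # coding SNPs are removed before truncation
  universe$coding[1:6000] <- TRUE
  got2 <- background_snps(universe, n = 10000, seed = 3)
  expect_equal(nrow(got2), 6000)
  expect_true(all(!got2$coding))
  expect_lte(nrow(background_snps(universe, n = 100, seed = 3)), 100)
})

test_that("scoring is invariant to fold order and respects window bounds", {
  cfg <- model_config(input_len = 220, output_len = 40, n_filters = 4,
                      conv_width = 11, n_dilated_layers = 2,
                      profile_width = 15)
  m1 <- structure(list(params = accvar:::init_params(cfg, 1), config = cfg,
                       cell_type = "rod", hold_out = 1), class = "accnet")
  m2 <- structure(list(params = accvar:::init_params(cfg, 2), config = cfg,
                       cell_type = "rod", hold_out = 2), class = "accnet")
  withr::with_seed(79, {
    seqs <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  })
  genome <- Biostrings::DNAStringSet(c(chr1 = seqs))
  ref <- substr(seqs, 1001, 1001)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  snps <- tibble::tibble(chrom = "chr1", pos = 1000L, rsid = "rs1",
                         ref = ref, alt = alt)
  models_ab <- tibble::tibble(cell_type = "rod", fold = 1:2,
                              model = list(m1, m2))
  models_ba <- tibble::tibble(cell_type = "rod", fold = 2:1,
                              model = list(m2, m1))
  s_ab <- score_alleles(snps, models_ab, genome)
  s_ba <- score_alleles(snps, models_ba, genome)
  expect_equal(s_ab$mean_log2fc, s_ba$mean_log2fc)
  expect_equal(s_ab$pred_ref, s_ba$pred_ref)
  # a SNP too close to the chromosome end is skipped and recorded
  edge <- tibble::tibble(chrom = "chr1", pos = 10L, rsid = "rs_edge",
                         ref = substr(seqs, 11, 11),
                         alt = setdiff(c("A", "C", "G", "T"),
                                       substr(seqs, 11, 11))[1])
  s <- score_alleles(edge, models_ab, genome)
  expect_equal(nrow(s), 0)
  expect_equal(attr(s, "skipped"), "rs_edge")
  # non-SNV input is rejected by validation
  bad <- dplyr::mutate(snps, alt = "AT")
  expect_error(score_alleles(bad, models_ab, genome), "single base")
})
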