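test_that("one-hot encoding maps bases to unit columns and N to zero", {
  m <- one_hot("ACGT")
  expect_equal(unname(m), diag(4))
  expect_equal(rownames(m), c("A", "C", "G", "T"))
  expect_equal(unname(one_hot("N")), matrix(0, 4, 1))
  # reverse-complement equivariance on random 50-mers
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  withr::with_seed(23, {
    for (i in 1:100) {
      s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
      expect_equal(accvar:::revcomp_onehot(one_hot(s)), one_hot(revcomp(s)))
    }
  })
})

test_that("MNLL equals the closed form and an independent log-pmf oracle", {
  # uniform probs over 4 bins, observed (1,1,1,1), coefficient kept:
  # -log(4!/(1!^4) * (1/4)^4) = 4 log 4 - log 24
  expect_equal(mnll_loss(rep(0.25, 4), rep(1, 4)), 4 * log(4) - log(24))
  # all-zero observation -> loss 0
  expect_equal(mnll_loss(rep(0.25, 4), rep(0, 4)), 0)
  # dropping the coefficient leaves only the -sum(y log p) term
  expect_equal(mnll_loss(rep(0.25, 4), rep(1, 4), include_coefficient = FALSE),
               4 * log(4))
  # oracle: stats::dmultinom on 50 random cases
  withr::with_seed(29, {
    for (i in 1:50) {
      k <- sample(3:12, 1)
      p <- runif(k); p <- p / sum(p)
      y <- rpois(k, 3)
      expect_equal(mnll_loss(p, y), -stats::dmultinom(y, prob = p, log = TRUE),
                   tolerance = 1e-8)
    }
  })
})

test_that("total loss reduces to MNLL at w = 0 and is minimized at the truth", {
  y <- c(3, 1, 0, 6)
  pred <- list(probs = y / sum(y), log_total = log1p(sum(y)))
  expect_equal(total_loss(pred, y, w = 0, include_coefficient = FALSE),
               mnll_loss(pred$probs, y, include_coefficient = FALSE))
  # perfect counts prediction removes the weighted term entirely
  expect_equal(total_loss(pred, y, w = 5, include_coefficient = FALSE),
               mnll_loss(y / sum(y), y, include_coefficient = FALSE))
  # a fully concentrated profile perfectly predicted gives exactly 0
  y1 <- c(0, 7, 0)
  expect_equal(total_loss(list(probs = c(0, 1, 0), log_total = log1p(7)),
                          y1, w = 3, include_coefficient = FALSE), 0)
  # the empirical profile is the MNLL optimum
  withr::with_seed(41, {
    for (i in 1:20) {
      q <- runif(4); q <- q / sum(q)
      expect_gte(mnll_loss(q, y), mnll_loss(y / sum(y), y))
    }
  })
})

test_that("network gradients match finite differences", {
  cfg <- model_config(input_len = 220, output_len = 40, n_filters = 6,
                      conv_width = 11, n_dilated_layers = 2,
                      profile_width = 15)
  withr::with_seed(7, {
    params <- accvar:::init_params(cfg, 7)
    seq <- paste(sample(c("A", "C", "G", "T"), 220, TRUE), collapse = "")
    X <- one_hot(seq)
    obs <- rpois(40, 3)
    w_cnt <- 2.5
    fwd <- accvar:::net_forward(params, X, cfg)
    g <- accvar:::net_backward(params, cfg, fwd, obs, w_cnt)
    lossfn <- function(p) {
      f <- accvar:::net_forward(p, X, cfg, keep_cache = FALSE)
      mnll_loss(f$probs, obs) + w_cnt * (f$log_total - log1p(sum(obs)))^2
    }
    eps <- 1e-5
    for (nm in names(params)) {
      idx <- if (length(params[[nm]]) > 4) sample(length(params[[nm]]), 4)
             else seq_along(params[[nm]])
      for (i in idx) {
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
        expect_equal(g[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("fold assignment is chromosome-disjoint, exhaustive and seeded", {
  regions <- tibble::tibble(chrom = rep(paste0("chr", 1:5), each = 4),
                            start = 1:20, end = 2:21)
  f1 <- make_folds(regions, n_folds = 5, seed = 1)
  # 5 chromosomes -> 5 single-chromosome folds
  expect_equal(sort(unique(f1$fold)), 1:5)
  expect_true(all(tapply(f1$fold, f1$chrom, function(x) length(unique(x))) == 1))
  expect_equal(length(unique(tapply(f1$fold, f1$chrom, unique))), 5)
  # partition: union of held-out sets = all regions, pairwise disjoint
  expect_equal(sort(unlist(lapply(1:5, function(k) which(f1$fold == k)))),
               seq_len(nrow(regions)))
  # deterministic across reruns
  expect_equal(make_folds(regions, 5, seed = 1), f1)
  expect_false(identical(make_folds(regions, 5, seed = 2)$fold, f1$fold))
  # fewer chromosomes than folds -> region-level fallback with warning
  two <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 6))
  expect_warning(f2 <- make_folds(two, n_folds = 4, seed = 1),
                 "region-level")
  expect_equal(sort(unique(f2$fold)), 1:4)
})

test_that("prediction returns a simplex profile deterministically", {
  cfg <- model_config(input_len = 220, output_len = 40, n_filters = 4,
                      conv_width = 11, n_dilated_layers = 2,
                      profile_width = 15)
  model <- structure(list(params = accvar:::init_params(cfg, 3),
                          config = cfg, cell_type = "rod", hold_out = 1),
                     class = "accnet")
  withr::with_seed(5, {
    seq <- paste(sample(c("A", "C", "G", "T"), 220, TRUE), collapse = "")
  })
  p1 <- predict(model, seq)
  expect_equal(sum(p1$probs), 1, tolerance = 1e-6)
  expect_true(all(p1$probs >= 0))
  expect_equal(p1$counts, exp(p1$log_total) * p1$probs)
  expect_identical(predict(model, seq), p1)      # identical input, output
  expect_error(predict(model, substr(seq, 1, 100)), "length")
})

test_that("training reduces the loss and learns the planted motif", {
  # small single-motif task: one cell type's peaks from a fixture with
  # enough peaks that the motif, not individual loci, carries the signal
  mo <- train_mo()
  ct <- mo$config$cell_types[1]
  repro <- reproducible_peaks(mo$replicate_peaks)
  kept <- qc_filter_cells(mo$cells)
  frags <- mo$fragments[mo$fragments$barcode %in% kept$barcode, ]
  track <- cell_type_tracks(frags, kept, mo$chrom_sizes)
  track <- track$track[[match(ct, track$cell_type)]]
  bg <- suppressWarnings(gc_matched_background(repro, mo$genome, seed = 2))
  regions <- dplyr::bind_rows(
    dplyr::mutate(repro[repro$cell_type == ct, c("chrom", "start", "end")],
                  is_peak = TRUE),
    dplyr::mutate(bg[repro$cell_type == ct, c("chrom", "start", "end")],
                  is_peak = FALSE))
  cfg <- model_config(input_len = 514, output_len = 200, jitter_bp = 100,
                      n_filters = 8, n_dilated_layers = 2, n_folds = 2,
                      epochs = 40, batch_peaks = 5, learning_rate = 0.02)
  regions <- suppressWarnings(make_folds(regions, 2, seed = 1))
  fit <- train_fold(mo$genome, track, regions, cfg, hold_out = 1, seed = 1,
                    cell_type = ct)
  h <- tidy(fit)
  expect_lt(mean(utils::tail(h$loss, 3)), mean(utils::head(h$loss, 3)))
  expect_equal(nrow(h), cfg$epochs)
  # inserting the planted motif into background raises predicted counts
  cons <- attr(mo$config$motifs[[mo$config$cell_type_motifs[[ct]]]],
               "consensus")
  half <- cfg$input_len %/% 2
  diffs <- vapply(seq_len(min(8, nrow(bg))), function(i) {
    c0 <- floor((bg$start[i] + bg$end[i]) / 2)
    s <- as.character(Biostrings::subseq(mo$genome[[bg$chrom[i]]],
                                         c0 - half + 1,
                                         c0 - half + cfg$input_len))
    mid <- half - nchar(cons) %/% 2
    s2 <- paste0(substr(s, 1, mid - 1), cons,
                 substr(s, mid + nchar(cons), cfg$input_len))
    predict(fit, s2)$log_total - predict(fit, s)$log_total
  }, numeric(1))
  expect_gt(mean(diffs), 0.3)
  # glance reports the fitted object's shape
  gl <- glance(fit)
  expect_equal(gl$epochs, cfg$epochs)
  expect_gt(gl$n_parameters, 0)

  # input attribution (gradient x input of the counts head) puts more
  # weight on planted motif bases than elsewhere in a peak window
  intact <- mo$motif_instances[mo$motif_instances$kind == "intact" &
                                 mo$motif_instances$cell_type == ct, ]
  ratios <- c()
  for (i in seq_len(nrow(intact))) {
    c0 <- floor((intact$start[i] + intact$end[i]) / 2)
    size <- mo$chrom_sizes$size[match(intact$chrom[i], mo$chrom_sizes$chrom)]
    if (c0 - half < 0 || c0 - half + cfg$input_len > size) next
    s <- as.character(Biostrings::subseq(mo$genome[[intact$chrom[i]]],
                                         c0 - half + 1,
                                         c0 - half + cfg$input_len))
    a <- abs(input_attribution(fit, s))
    in_motif <- seq(half - 6, half + 6)
    ratios <- c(ratios, mean(a[in_motif]) / mean(a[-in_motif]))
  }
  expect_gt(stats::median(ratios), 1.5)
})
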