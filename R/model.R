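#' One-hot encode a DNA sequence
#'
#' A, C, G, T map to unit columns (rows in that order); any other letter
#' (N) maps to an all-zero column, so
#' `revcomp(one_hot(s)) == one_hot(revcomp(s))`.
#'
#' @param seq A character string over ACGTN.
#' @return A 4 x nchar(seq) numeric matrix with rownames A, C, G, T.
#' @export
one_hot <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  m <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(chars, c("A", "C", "G", "T"))
  ok <- which(!is.na(idx))
  m[cbind(idx[ok], ok)] <- 1
  m
}

# Reverse complement of a one-hot matrix: reverse positions, swap A<->T
# and C<->G (i.e. flip row order, keeping canonical row labels).
revcomp_onehot <- function(m) {
  out <- m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- rownames(m)
  out
}

#' Multinomial negative log likelihood of a profile
#'
#' `-log Multinomial(observed | n = sum(observed), p = probs)`. The
#' multinomial coefficient is included by default (it is constant in the
#' model parameters, so it does not affect optimization, but makes the
#' reported loss the exact negative log pmf). Probabilities of exactly 0
#' at a nonzero-count base are clamped at 1e-12.
#'
#' @param probs Probability vector (sums to 1).
#' @param observed Non-negative count vector, same length.
#' @param include_coefficient Keep the log multinomial coefficient?
#' @return A single number; 0 when all observed counts are zero (with
#'   coefficient included).
#' @export
mnll_loss <- function(probs, observed, include_coefficient = TRUE) {
  stopifnot(length(probs) == length(observed), all(observed >= 0))
  n <- sum(observed)
  p <- pmax(probs, 1e-12)
  ll <- sum(observed * log(p))
  if (include_coefficient) {
    ll <- ll + lgamma(n + 1) - sum(lgamma(observed + 1))
  }
  -ll
}

#' Combined profile + counts training loss
#'
#' `MNLL(probs, obs) + w * (log_total_pred - log(1 + sum(obs)))^2`, with
#' `w` the counts-loss weight (0.1 times the mean total counts per
#' training region, computed by the trainer).
#'
#' @param pred A list with `probs` and `log_total` (a
#'   [predict.accnet()] result).
#' @param obs Observed count vector over the output window.
#' @param w Counts-loss weight.
#' @param include_coefficient Passed to [mnll_loss()].
#' @return A single number.
#' @export
total_loss <- function(pred, obs, w, include_coefficient = TRUE) {
  mnll_loss(pred$probs, obs, include_coefficient) +
    w * (pred$log_total - log1p(sum(obs)))^2
}

#' Model architecture and training configuration
#'
#' A convolutional profile model: a wide first convolution, a stack of
#' exponentially dilated residual convolutions, a profile head (softmax
#' over the centred output window) and a log-counts head (linear on
#' pooled trunk features; mean pooling concatenated with per-filter max
#' pooling, so a single localized motif can move the predicted total).
#' All convolutions are "valid"; the config checks that enough positions
#' survive to cover the output window.
#'
#' @param input_len,output_len Input and centred output window (bp).
#' @param n_filters Filters per convolutional layer.
#' @param conv_width First-layer filter width.
#' @param n_dilated_layers Dilated residual layers (dilation 2^i).
#' @param dilated_width Dilated filter width.
#' @param profile_width Profile-head filter width.
#' @param counts_loss_weight_factor Counts-loss weight is this factor
#'   times the mean total counts per training region.
#' @param n_folds Cross-validation folds (chromosome-disjoint).
#' @param jitter_bp Max training-window jitter on either side.
#' @param revcomp_prob Probability of reverse-complementing an example.
#' @param peak_to_nonpeak_ratio Peaks per non-peak region in each batch.
#' @param batch_peaks Peak examples per batch.
#' @param epochs,learning_rate Adam training schedule.
#' @param weight_decay Decoupled L2 weight decay applied to convolution
#'   weights at each update (regularizes toward motif-driven rather than
#'   locus-memorizing solutions on small region sets).
#' @param include_coefficient Keep the multinomial coefficient in
#'   reported MNLL values.
#' @return A `model_config` list.
#' @export
model_config <- function(input_len = 2114, output_len = 1000,
                         n_filters = 64, conv_width = 21,
                         n_dilated_layers = 4, dilated_width = 3,
                         profile_width = 25,
                         counts_loss_weight_factor = 0.1,
                         n_folds = 5, jitter_bp = 500,
                         revcomp_prob = 0.5,
                         peak_to_nonpeak_ratio = 10,
                         batch_peaks = 20, epochs = 20,
                         learning_rate = 0.004,
                         weight_decay = 1e-4,
                         include_coefficient = TRUE) {
  stopifnot(input_len >= output_len)
  dil <- 2^seq_len(n_dilated_layers)
  trunk_len <- input_len - (conv_width - 1) -
    sum((dilated_width - 1) * dil)
  prof_len <- trunk_len - (profile_width - 1)
  if (prof_len < output_len) {
    abort("model_config: receptive-field shrinkage leaves fewer positions than output_len")
  }
  cfg <- as.list(environment())
  cfg$dilations <- dil
  cfg$trunk_len <- trunk_len
  cfg$prof_len <- prof_len
  cfg$crop_offset <- (prof_len - output_len) %/% 2
  structure(cfg, class = "model_config")
}

# ---- low-level conv machinery -------------------------------------------

# Unfold X (C x L) into (C*w) x L_out columns for a width-w dilation-d
# valid convolution; block k of C rows holds positions offset (k-1)*d.
im2col <- function(X, w, d) {
  C <- nrow(X); L <- ncol(X)
  L_out <- L - (w - 1) * d
  M <- matrix(0, C * w, L_out)
  for (k in seq_len(w)) {
    M[((k - 1) * C + 1):(k * C), ] <-
      X[, ((k - 1) * d + 1):((k - 1) * d + L_out), drop = FALSE]
  }
  M
}

# Adjoint of im2col: scatter column gradients back onto the input.
col2im <- function(dM, C, w, d, L) {
  L_out <- L - (w - 1) * d
  dX <- matrix(0, C, L)
  for (k in seq_len(w)) {
    cols <- ((k - 1) * d + 1):((k - 1) * d + L_out)
    dX[, cols] <- dX[, cols] + dM[((k - 1) * C + 1):(k * C), , drop = FALSE]
  }
  dX
}

init_params <- function(cfg, seed) {
  withr::with_seed(seed, {
    nf <- cfg$n_filters
    he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc)
    params <- list(W1 = he(nf, 4 * cfg$conv_width), b1 = numeric(nf))
    for (i in seq_len(cfg$n_dilated_layers)) {
      params[[paste0("Wd", i)]] <- he(nf, nf * cfg$dilated_width)
      params[[paste0("bd", i)]] <- numeric(nf)
    }
    params$Wp <- he(1, nf * cfg$profile_width) * 0.1
    params$bp <- 0
    params$Wc <- rnorm(2 * nf, sd = 0.1)  # [mean-pool | max-pool]
    params$bc <- 0
    params
  })
}

# Forward pass; returns prediction plus cached activations for backward.
net_forward <- function(params, X, cfg, keep_cache = TRUE) {
  cache <- list(X = X)
  C1 <- im2col(X, cfg$conv_width, 1L)
  Z1 <- params$W1 %*% C1 + params$b1
  A <- Z1 * (Z1 > 0)
  if (keep_cache) { cache$C1 <- C1; cache$Z1 <- Z1 }
  Ls <- ncol(A)
  for (i in seq_len(cfg$n_dilated_layers)) {
    d <- cfg$dilations[i]
    Ci <- im2col(A, cfg$dilated_width, d)
    Zi <- params[[paste0("Wd", i)]] %*% Ci + params[[paste0("bd", i)]]
    Hi <- Zi * (Zi > 0)
    A_crop <- A[, (d + 1):(Ls - d), drop = FALSE]
    if (keep_cache) {
      cache[[paste0("C", i + 1)]] <- Ci
      cache[[paste0("Z", i + 1)]] <- Zi
      cache[[paste0("Lin", i)]] <- Ls
    }
    A <- A_crop + Hi
    Ls <- ncol(A)
  }
  cache$A_top <- A
  Cp <- im2col(A, cfg$profile_width, 1L)
  zp <- as.numeric(params$Wp %*% Cp) + params$bp
  z <- zp[(cfg$crop_offset + 1):(cfg$crop_offset + cfg$output_len)]
  zmax <- max(z)
  ez <- exp(z - zmax)
  probs <- ez / sum(ez)
  max_idx <- max.col(A, ties.method = "first")
  feat <- c(rowMeans(A), A[cbind(seq_len(nrow(A)), max_idx)])
  log_total <- sum(params$Wc * feat) + params$bc
  if (keep_cache) {
    cache$Cp <- Cp; cache$probs <- probs
    cache$feat <- feat; cache$max_idx <- max_idx
  }
  list(probs = probs, log_total = log_total, cache = cache)
}

# Backward pass for one example; returns parameter gradients (and the
# input gradient when requested, used for attribution).
net_backward <- function(params, cfg, fwd, obs, w_cnt,
                         want_input_grad = FALSE,
                         counts_only = FALSE) {
  cache <- fwd$cache
  g <- list()
  A <- cache$A_top
  Ltop <- ncol(A)
  # profile head
  if (!counts_only) {
    n_obs <- sum(obs)
    dz <- n_obs * fwd$probs - obs
    dzp <- numeric(cfg$prof_len)
    dzp[(cfg$crop_offset + 1):(cfg$crop_offset + cfg$output_len)] <- dz
    dzp <- matrix(dzp, 1)
    g$Wp <- dzp %*% t(cache$Cp)
    g$bp <- sum(dzp)
    dCp <- t(params$Wp) %*% dzp
    dA <- col2im(dCp, cfg$n_filters, cfg$profile_width, 1L, Ltop)
  } else {
    g$Wp <- matrix(0, 1, ncol(params$Wp)); g$bp <- 0
    dA <- matrix(0, cfg$n_filters, Ltop)
  }
  # counts head: mean-pool part spreads uniformly, max-pool part routes
  # to each filter's argmax position
  dlog <- if (counts_only) 1 else 2 * w_cnt * (fwd$log_total - log1p(sum(obs)))
  g$Wc <- dlog * cache$feat
  g$bc <- dlog
  nf <- cfg$n_filters
  dA <- dA + matrix(params$Wc[seq_len(nf)] * dlog / Ltop, nf, Ltop)
  dA[cbind(seq_len(nf), cache$max_idx)] <-
    dA[cbind(seq_len(nf), cache$max_idx)] +
    params$Wc[nf + seq_len(nf)] * dlog
  # dilated residual stack, in reverse
  for (i in rev(seq_len(cfg$n_dilated_layers))) {
    d <- cfg$dilations[i]
    Zi <- cache[[paste0("Z", i + 1)]]
    dZ <- dA * (Zi > 0)
    g[[paste0("Wd", i)]] <- dZ %*% t(cache[[paste0("C", i + 1)]])
    g[[paste0("bd", i)]] <- rowSums(dZ)
    L_in <- cache[[paste0("Lin", i)]]
    dC <- t(params[[paste0("Wd", i)]]) %*% dZ
    dA_prev <- col2im(dC, cfg$n_filters, cfg$dilated_width, d, L_in)
    dA_prev[, (d + 1):(L_in - d)] <- dA_prev[, (d + 1):(L_in - d)] + dA
    dA <- dA_prev
  }
  dZ1 <- dA * (cache$Z1 > 0)
  g$W1 <- dZ1 %*% t(cache$C1)
  g$b1 <- rowSums(dZ1)
  if (want_input_grad) {
    dC1 <- t(params$W1) %*% dZ1
    g$input <- col2im(dC1, 4L, cfg$conv_width, 1L, ncol(cache$X))
  }
  g
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  decayed <- c("W1", "Wp", "Wc", grep("^Wd", names(params), value = TRUE))
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    if (weight_decay > 0 && nm %in% decayed) {
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Chromosome-disjoint cross-validation folds
#'
#' Regions on one chromosome always share a fold. When there are fewer
#' chromosomes than folds, falls back to a region-level disjoint split
#' with a warning. Deterministic given `seed`; every fold's held-out set
#' is non-empty.
#'
#' @param regions Tibble with a `chrom` column.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return `regions` with an integer `fold` column (1..n_folds).
#' @export
make_folds <- function(regions, n_folds = 5, seed = 1) {
  assert_cols(regions, "chrom")
  chroms <- sort(unique(regions$chrom))
  withr::with_seed(derive_seed(seed, "folds"), {
    if (length(chroms) >= n_folds) {
      perm <- sample(chroms)
      fold_of <- setNames(rep(seq_len(n_folds),
                              length.out = length(perm)), perm)
      regions$fold <- as.integer(fold_of[regions$chrom])
    } else {
      warn(sprintf("make_folds: %d chromosome(s) < %d folds; falling back to region-level split",
                   length(chroms), n_folds))
      perm <- sample(nrow(regions))
      fold <- integer(nrow(regions))
      fold[perm] <- rep(seq_len(n_folds), length.out = nrow(regions))
      regions$fold <- fold
    }
  })
  if (length(unique(regions$fold)) < n_folds) {
    abort("make_folds: some fold has an empty held-out set")
  }
  regions
}

# Observed insertion counts in the length-`len` window starting at
# 0-based `start` on `chrom`.
track_window <- function(track, chrom, start, len) {
  track$counts[[chrom]][(start + 1):(start + len)]
}

#' Train one model fold
#'
#' Trains the convolutional profile model on the peak and background
#' regions whose fold differs from `hold_out`. Each epoch, peak examples
#' are jittered by up to `jitter_bp` on either side, a random half of
#' examples are reverse-complemented, and each batch carries a 10:1
#' ratio of peaks to non-peak regions. Loss is profile MNLL plus
#' weighted squared error on `log(1 + total counts)`, with weight
#' `counts_loss_weight_factor` times the mean total counts per training
#' region.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param track An `insertion_track` for the cell type being modelled.
#' @param regions Tibble of candidate regions with `chrom`, `start`,
#'   `end`, `is_peak` and a `fold` column from [make_folds()]; windows
#'   are centred on region centres. Regions whose input window would
#'   leave the chromosome are dropped (counted in the result).
#' @param cfg A [model_config()].
#' @param hold_out Fold id to exclude from training.
#' @param seed Integer seed (initialization, shuffling, augmentation).
#' @param cell_type Label stored in the fitted object.
#' @return An object of class `accnet`: parameters, config, training
#'   history, counts-loss weight, and bookkeeping.
#' @export
train_fold <- function(genome, track, regions, cfg = model_config(),
                       hold_out = 1, seed = 1, cell_type = NA_character_) {
  assert_cols(regions, c("chrom", "start", "end", "is_peak", "fold"))
  sizes <- chrom_sizes_of(genome)
  half_in <- cfg$input_len %/% 2
  centre <- floor((regions$start + regions$end) / 2)
  margin <- half_in + cfg$jitter_bp + 1
  fits <- centre - margin >= 0 &
    centre + margin <= sizes$size[match(regions$chrom, sizes$chrom)]
  n_dropped <- sum(!fits)
  regions <- regions[fits, ]
  centre <- centre[fits]
  train <- regions$fold != hold_out
  peak_idx <- which(train & regions$is_peak)
  bg_idx <- which(train & !regions$is_peak)
  if (length(peak_idx) == 0) abort("train_fold: no training peaks")

  # counts-loss weight from the training peaks, unjittered
  totals <- map_dbl(peak_idx, function(i) {
    sum(track_window(track, regions$chrom[i],
                     centre[i] - cfg$output_len %/% 2, cfg$output_len))
  })
  w_cnt <- cfg$counts_loss_weight_factor * mean(totals)

  params <- init_params(cfg, derive_seed(seed, "init"))
  state <- list(m = map(params, ~ .x * 0), v = map(params, ~ .x * 0))
  t_step <- 0
  n_bg_per_batch <- max(1L, round(cfg$batch_peaks / cfg$peak_to_nonpeak_ratio))
  history <- vector("list", cfg$epochs)

  fetch_example <- function(i, jit) {
    ch <- regions$chrom[i]
    c0 <- centre[i] + jit
    seq <- as.character(Biostrings::subseq(genome[[ch]],
                                           c0 - half_in + 1,
                                           c0 - half_in + cfg$input_len))
    X <- one_hot(seq)
    y <- track_window(track, ch, c0 - cfg$output_len %/% 2, cfg$output_len)
    list(X = X, y = y)
  }

  withr::with_seed(derive_seed(seed, "train"), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(peak_idx)
      ep_loss <- ep_mnll <- ep_cnt <- 0
      n_ex <- 0
      for (b0 in seq(1, length(ord), by = cfg$batch_peaks)) {
        batch <- ord[b0:min(b0 + cfg$batch_peaks - 1, length(ord))]
        if (length(bg_idx) > 0) {
          batch <- c(batch, sample(bg_idx, min(n_bg_per_batch,
                                               length(bg_idx))))
        }
        grads <- NULL
        for (i in batch) {
          jit <- sample.int(2 * cfg$jitter_bp + 1, 1) - cfg$jitter_bp - 1
          ex <- fetch_example(i, jit)
          if (runif(1) < cfg$revcomp_prob) {
            ex$X <- revcomp_onehot(ex$X)
            ex$y <- rev(ex$y)
          }
          fwd <- net_forward(params, ex$X, cfg)
          g <- net_backward(params, cfg, fwd, ex$y, w_cnt)
          mnll <- mnll_loss(fwd$probs, ex$y, cfg$include_coefficient)
          cntl <- w_cnt * (fwd$log_total - log1p(sum(ex$y)))^2
          ep_mnll <- ep_mnll + mnll
          ep_cnt <- ep_cnt + cntl
          ep_loss <- ep_loss + mnll + cntl
          n_ex <- n_ex + 1
          grads <- if (is.null(grads)) g
                   else purrr::map2(grads, g[names(grads)], `+`)
        }
        grads <- map(grads, ~ .x / length(batch))
        t_step <- t_step + 1
        upd <- adam_step(params, grads, state, cfg$learning_rate, t_step,
                         weight_decay = cfg$weight_decay)
        params <- upd$params
        state <- upd$state
      }
      history[[epoch]] <- tibble(epoch = epoch, loss = ep_loss / n_ex,
                                 mnll = ep_mnll / n_ex,
                                 counts_loss = ep_cnt / n_ex)
    }
  })
  structure(list(params = params, config = cfg, cell_type = cell_type,
                 hold_out = hold_out, seed = seed, w_cnt = w_cnt,
                 n_dropped_edge = n_dropped,
                 train_chroms = sort(unique(regions$chrom[train])),
                 history = bind_rows(history)),
            class = "accnet")
}

#' @export
print.accnet <- function(x, ...) {
  cat(sprintf("<accnet> cell type %s, held-out fold %s; final loss %.3f after %d epochs\n",
              x$cell_type, x$hold_out, tail(x$history$loss, 1),
              nrow(x$history)))
  invisible(x)
}

#' Predict profile and log counts for a sequence
#'
#' @param object An `accnet` model.
#' @param sequence A character string of exactly `input_len` bases, or a
#'   4 x input_len one-hot matrix.
#' @param ... Unused.
#' @return List with `probs` (length `output_len`, sums to 1),
#'   `log_total`, and `counts` (`exp(log_total) * probs`).
#' @export
predict.accnet <- function(object, sequence, ...) {
  X <- if (is.character(sequence)) one_hot(sequence) else sequence
  if (ncol(X) != object$config$input_len) {
    abort(sprintf("predict.accnet: sequence length %d != input_len %d",
                  ncol(X), object$config$input_len))
  }
  fwd <- net_forward(object$params, X, object$config, keep_cache = FALSE)
  list(probs = fwd$probs, log_total = fwd$log_total,
       counts = exp(fwd$log_total) * fwd$probs)
}

#' Per-base input attribution of the counts head
#'
#' Gradient-times-input of `log_total` with respect to the one-hot
#' input; used for reporting which bases drive predicted accessibility.
#'
#' @param object An `accnet` model.
#' @param sequence Sequence string or one-hot matrix of `input_len`.
#' @return Numeric vector of per-base attributions (length `input_len`).
#' @export
input_attribution <- function(object, sequence) {
  X <- if (is.character(sequence)) one_hot(sequence) else sequence
  fwd <- net_forward(object$params, X, object$config)
  g <- net_backward(object$params, object$config, fwd,
                    obs = numeric(object$config$output_len), w_cnt = 0,
                    want_input_grad = TRUE, counts_only = TRUE)
  colSums(g$input * X)
}

#' Train models for every cell type and fold
#'
#' @param genome Genome.
#' @param tracks Tibble from [cell_type_tracks()] (`cell_type`, `track`).
#' @param peaks Reproducible peak tibble (`chrom`, `start`, `end`,
#'   `cell_type`).
#' @param backgrounds GC-matched background tibble aligned to `peaks`
#'   (from [gc_matched_background()], any cell type split done by the
#'   caller), with `chrom`, `start`, `end`, `cell_type`.
#' @param cfg A [model_config()].
#' @param seed Integer seed.
#' @return Tibble `cell_type`, `fold`, `model` (list-column of `accnet`).
#' @export
train_models <- function(genome, tracks, peaks, backgrounds,
                         cfg = model_config(), seed = 1) {
  out <- list()
  for (ct in tracks$cell_type) {
    track <- tracks$track[[match(ct, tracks$cell_type)]]
    regions <- bind_rows(
      mutate(peaks[peaks$cell_type == ct, c("chrom", "start", "end")],
             is_peak = TRUE),
      mutate(backgrounds[backgrounds$cell_type == ct,
                         c("chrom", "start", "end")],
             is_peak = FALSE))
    regions <- suppressWarnings(
      make_folds(regions, cfg$n_folds, derive_seed(seed, ct)))
    for (f in seq_len(cfg$n_folds)) {
      model <- train_fold(genome, track, regions, cfg, hold_out = f,
                          seed = derive_seed(seed, paste0(ct, f)),
                          cell_type = ct)
      out[[length(out) + 1]] <- tibble(cell_type = ct, fold = f,
                                       model = list(model))
    }
  }
  bind_rows(out)
}
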