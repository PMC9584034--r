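#' Built-in position weight matrices for the synthetic multiome
#'
#' Four sharp 8-12 bp PWMs loosely shaped like TF families active in
#' retinal cell types (an OTX-like homeodomain site, a TAAT homeodomain
#' core, a bHLH E-box, and a longer zinc-finger-like site). Shipped as
#' explicit matrices so the generator has no external dependency.
#'
#' @param conf Probability placed on the consensus base at each position
#'   (the remainder is split over the other three bases).
#' @return A named list of 4 x width probability matrices (rows A, C, G,
#'   T, columns summing to 1), each with attribute `consensus`.
#' @export
default_motifs <- function(conf = 0.94) {
  consensus <- c(
    otx_like  = "GGATTAGC",
    hd_taat   = "CTAATTAG",
    ebox_bhlh = "AACAGCTGTT",
    zf_like   = "TGCCACCTGGTG"
  )
  lapply(consensus, function(s) pwm_from_consensus(s, conf = conf))
}

#' Build a PWM from a consensus string
#'
#' @param s Consensus sequence (ACGT).
#' @param conf Probability of the consensus base per position.
#' @return A 4 x nchar(s) probability matrix with rows A, C, G, T.
#' @export
pwm_from_consensus <- function(s, conf = 0.94) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(toupper(s), "")[[1]]
  stopifnot(all(chars %in% bases))
  m <- matrix((1 - conf) / 3, nrow = 4, ncol = length(chars),
              dimnames = list(bases, NULL))
  for (j in seq_along(chars)) m[chars[j], j] <- conf
  attr(m, "consensus") <- paste(chars, collapse = "")
  m
}

#' Log-likelihood score of a sequence under a PWM
#'
#' @param pwm A 4 x w probability matrix (rows A, C, G, T).
#' @param seq A string of length `ncol(pwm)`.
#' @return Sum of log base probabilities.
#' @export
pwm_score <- function(pwm, seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  stopifnot(length(chars) == ncol(pwm))
  sum(log(pwm[cbind(match(chars, rownames(pwm)), seq_along(chars))]))
}

# Position with the highest information content (lowest column entropy);
# ties broken by the leftmost position.
pwm_max_info_position <- function(pwm) {
  ent <- apply(pwm, 2, function(p) -sum(p * log(p)))
  which.min(ent)
}

# Lowest-probability base in a PWM column.
pwm_worst_base <- function(pwm, j) {
  rownames(pwm)[which.min(pwm[, j])]
}
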