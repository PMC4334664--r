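# Real-valued data features from complex cross-spectral densities.
#
# Ordering (deterministic, documented): frequencies in ascending order; at
# each frequency the upper triangle including the diagonal in row-major
# order; diagonal entries contribute their real part only, off-diagonal
# entries contribute real part then imaginary part. For C channels this
# gives C^2 features per frequency.

#' Feature vector of a cross-spectral density
#'
#' Concatenates real and imaginary parts of the upper-triangular CSD entries
#' across frequencies into a real vector, together with a channel-pair block
#' label per feature (used for the block-diagonal noise precision).
#'
#' @param csd a [csd_data()] object
#' @return list with `y` (numeric vector), `block` (factor of channel-pair
#'   labels `"i_j"`), `pair_i`, `pair_j`, `freq_index`, and `n_channels`
#' @export
csd_features <- function(csd) {
  stopifnot(inherits(csd, "csd_data"))
  C <- length(csd$channels)
  nf <- length(csd$freq)
  y <- c(); blk <- c(); pi_ <- c(); pj_ <- c(); fi <- c()
  per <- list()
  idx <- 1
  for (i in seq_len(C)) for (j in i:C) {
    per[[idx]] <- list(i = i, j = j)
    idx <- idx + 1
  }
  nfeat_per_f <- C + C * (C - 1)
  y <- numeric(nf * nfeat_per_f)
  blk <- character(nf * nfeat_per_f)
  pi_ <- integer(length(y)); pj_ <- integer(length(y)); fi <- integer(length(y))
  pos <- 1
  for (k in seq_len(nf)) {
    for (p in per) {
      i <- p$i; j <- p$j
      lab <- paste(i, j, sep = "_")
      if (i == j) {
        y[pos] <- Re(csd$csd[k, i, j])
        blk[pos] <- lab; pi_[pos] <- i; pj_[pos] <- j; fi[pos] <- k
        pos <- pos + 1
      } else {
        y[pos] <- Re(csd$csd[k, i, j])
        y[pos + 1] <- Im(csd$csd[k, i, j])
        blk[pos:(pos + 1)] <- lab
        pi_[pos:(pos + 1)] <- i; pj_[pos:(pos + 1)] <- j
        fi[pos:(pos + 1)] <- k
        pos <- pos + 2
      }
    }
  }
  list(y = y, block = factor(blk), pair_i = pi_, pair_j = pj_,
       freq_index = fi, n_channels = C)
}

# Rebuild a csd_data object from a feature vector (inverse of csd_features
# for the documented ordering).
features_to_csd <- function(y, freq, n_channels, channels = NULL) {
  C <- n_channels
  nf <- length(freq)
  G <- array(0i, c(nf, C, C))
  pos <- 1
  for (k in seq_len(nf)) {
    for (i in seq_len(C)) for (j in i:C) {
      if (i == j) {
        G[k, i, j] <- complex(real = y[pos])
        pos <- pos + 1
      } else {
        G[k, i, j] <- complex(real = y[pos], imaginary = y[pos + 1])
        G[k, j, i] <- Conj(G[k, i, j])
        pos <- pos + 2
      }
    }
  }
  csd_data(G, freq, channels)
}
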