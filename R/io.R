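# Plain-text serialization: CSV bundles for cross-spectral and epoched
# data, JSON for fits and comparisons.

#' Write a cross-spectral density to CSV
#'
#' One row per frequency; columns `re_i_j` for every upper-triangular pair
#' and `im_i_j` for off-diagonal pairs, with metadata (channels, epoch
#' count, sampling rate) in `#`-prefixed header lines. Round-trips through
#' [read_csd_csv()].
#'
#' @param x a [csd_data()] object
#' @param path output file path
#' @export
write_csd_csv <- function(x, path) {
  stopifnot(inherits(x, "csd_data"))
  C <- length(x$channels)
  df <- data.frame(freq = x$freq)
  for (i in seq_len(C)) for (j in i:C) {
    df[[paste0("re_", i, "_", j)]] <- Re(x$csd[, i, j])
    if (i != j) df[[paste0("im_", i, "_", j)]] <- Im(x$csd[, i, j])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#channels: ", paste(x$channels, collapse = ",")),
               paste0("#n_epochs: ", x$n_epochs),
               paste0("#fs: ", x$fs)), con)
  write.csv(df, con, row.names = FALSE)
}

#' Read a cross-spectral density from CSV
#'
#' @param path file written by [write_csd_csv()]
#' @return a [csd_data()] object
#' @export
read_csd_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- sub("^#[a-z_]+: ", "", hdr)
  channels <- strsplit(meta[1], ",")[[1]]
  n_epochs <- suppressWarnings(as.integer(meta[2]))
  fs <- suppressWarnings(as.numeric(meta[3]))
  df <- read.csv(path, comment.char = "#")
  C <- length(channels)
  G <- array(0i, c(nrow(df), C, C))
  for (i in seq_len(C)) for (j in i:C) {
    re <- df[[paste0("re_", i, "_", j)]]
    im <- if (i == j) 0 else df[[paste0("im_", i, "_", j)]]
    G[, i, j] <- complex(real = re, imaginary = im)
    if (i != j) G[, j, i] <- Conj(G[, i, j])
  }
  csd_data(G, df$freq, channels, n_epochs, fs)
}

#' Write epoched time series to CSV
#'
#' Long format (`epoch`, `channel`, `sample`, `value`) with the sampling
#' rate in a `#`-prefixed header line.
#'
#' @param x an [epoched_ts()] object
#' @param path output file path
#' @export
write_epochs_csv <- function(x, path) {
  stopifnot(inherits(x, "epoched_ts"))
  d <- dim(x$data)
  df <- data.frame(epoch = rep(seq_len(d[1]), each = d[2] * d[3]),
                   channel = rep(rep(seq_len(d[2]), each = d[3]), d[1]),
                   sample = rep(seq_len(d[3]), d[1] * d[2]),
                   value = as.vector(aperm(x$data, c(3, 2, 1))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#fs: ", x$fs), con)
  write.csv(df, con, row.names = FALSE)
}

#' Read epoched time series from CSV
#'
#' @param path file written by [write_epochs_csv()]
#' @return an [epoched_ts()] object
#' @export
read_epochs_csv <- function(path) {
  fs <- as.numeric(sub("^#fs: ", "", readLines(path, n = 1)))
  df <- read.csv(path, comment.char = "#")
  E <- max(df$epoch); C <- max(df$channel); S <- max(df$sample)
  arr <- array(0, c(E, C, S))
  arr[cbind(df$epoch, df$channel, df$sample)] <- df$value
  epoched_ts(arr, fs)
}

#' Serialize a model fit to JSON
#'
#' Writes posterior means, the diagonal of the posterior covariance, noise
#' log-precisions, free energy with its accuracy/complexity split, the
#' convergence trace, and the direction.
#'
#' @param fit a [fit_csd()] result
#' @param path output file path
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cmc_fit"))
  out <- list(direction = fit$direction, mu = as.list(fit$mu),
              sigma_diag = as.list(setNames(diag(fit$Sigma),
                                            rownames(fit$Sigma))),
              lambda = as.list(fit$lambda),
              F = fit$F, accuracy = fit$accuracy, complexity = fit$complexity,
              converged = fit$converged, iterations = fit$iterations,
              trace = fit$trace)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
}

#' Serialize a model comparison to JSON
#'
#' @param cmp a [compare_models()] result
#' @param path output file path
#' @export
write_comparison_json <- function(cmp, path) {
  stopifnot(inherits(cmp, "cmc_comparison"))
  out <- list(summary = cmp$summary, dF = cmp$dF, d_reduced = cmp$d_reduced,
              selected = cmp$selected, partial = cmp$partial)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
}
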