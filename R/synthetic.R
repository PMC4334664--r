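# Synthetic data: prior sampling with stability rejection, CSD-level
# datasets with complex noise at a stated log precision, and time-domain
# stochastic simulation serving as an independent oracle for the spectral
# forward model.

# Real-valued colored noise with a given one-sided PSD (power per Hz),
# generated by frequency-domain amplitude shaping of white Gaussian noise.
colored_noise <- function(n, fs, psd) {
  nh <- floor(n / 2)
  f <- fs * seq_len(nh) / n
  S <- psd(f)
  X <- complex(real = numeric(n))
  amp <- sqrt(S * fs * n / 2)
  z <- complex(real = rnorm(nh), imaginary = rnorm(nh)) / sqrt(2)
  if (n %% 2 == 0) z[nh] <- complex(real = rnorm(1)) # Nyquist bin is real
  X[1 + seq_len(nh)] <- amp * z
  X[n + 1 - seq_len(if (n %% 2 == 0) nh - 1 else nh)] <-
    Conj(X[1 + seq_len(if (n %% 2 == 0) nh - 1 else nh)])
  Re(fft(X, inverse = TRUE)) / n
}

#' Draw model parameters from the prior
#'
#' Samples log-deviations `theta ~ Normal(0, v)` per parameter and rejects
#' draws whose delay-free linearization is unstable (an eigenvalue with
#' nonnegative real part), so every returned draw supports a spectral
#' prediction.
#'
#' @param priors a [cmc_priors()] object
#' @param seed integer seed
#' @param direction hierarchy direction used for the stability check
#' @param config model configuration
#' @param max_attempts rejection budget
#' @return named vector of log-deviations
#' @export
sample_prior <- function(priors = cmc_priors(), seed = 1,
                         direction = "veridical", config = cmc_config(),
                         max_attempts = 100) {
  set.seed(seed)
  for (a in seq_len(max_attempts)) {
    theta <- setNames(rnorm(length(priors$mean), 0, sqrt(priors$var)),
                      names(priors$mean))
    sys <- system_matrices(theta, direction, priors, config)
    if (stability_check(sys, "logical")) return(theta)
  }
  stop("rejection budget exhausted: no stable prior draw in ",
       max_attempts, " attempts")
}

#' Generate a synthetic cross-spectral dataset
#'
#' Predicts the CSD at the given parameters and mixes it with complex
#' Gaussian noise scaled so that the ratio of total signal variance to total
#' noise variance equals `exp(log_precision)` over the data features, with
#' per-feature noise allocated proportionally to the mean signal power at
#' each frequency. Hermitian structure is preserved exactly. Log precisions
#' of 30 or more are treated as noiseless.
#'
#' @param theta generative parameters (named log-deviations)
#' @param freq frequency grid (default from `config`)
#' @param log_precision log of the signal-to-noise variance ratio
#' @param seed integer seed
#' @param direction generative hierarchy direction
#' @param priors,config model priors and configuration
#' @return object of class `cmc_synth`: list with the generative `theta`,
#'   `direction`, noisy `csd`, `log_precision`, and `seed`
#' @export
generate_dataset <- function(theta = NULL, freq = NULL, log_precision = 7,
                             seed = 1, direction = "veridical",
                             priors = cmc_priors(), config = cmc_config()) {
  stopifnot(is.finite(log_precision))
  if (is.null(freq)) freq <- config$freq
  if (is.null(theta)) theta <- cmc_theta(priors)
  g <- predict_csd(theta, freq, direction, priors, config)
  feats <- csd_features(g)
  y <- feats$y
  if (log_precision < 30) {
    set.seed(seed)
    w <- as.numeric(tapply(y^2, feats$freq_index, mean))[feats$freq_index]
    v <- w * (sum(y^2) / exp(log_precision)) / sum(w)
    y <- y + rnorm(length(y), 0, sqrt(v))
  }
  csd <- features_to_csd(y, freq, feats$n_channels, g$channels)
  structure(list(theta = theta, direction = direction, csd = csd,
                 log_precision = log_precision, seed = seed),
            class = "cmc_synth")
}

#' Simulate the network in the time domain
#'
#' Stochastic Heun (improved Euler) integration (step `config$sim_dt`) of
#' the linearized
#' (default) or full nonlinear stochastic dynamics, driven by endogenous
#' fluctuations with the parameterized input spectra (colored noise from
#' frequency-domain spectral shaping), with the extrinsic conduction delay
#' implemented by a delay buffer. Channel observations apply the electrode
#' gains and population weights; channel-specific and common observation
#' noise with the modeled spectra can be added. The output is chopped into
#' equal-length epochs after discarding a burn-in.
#'
#' @param theta model parameters (named log-deviations)
#' @param duration output duration, seconds
#' @param fs output sampling rate, Hz (must divide `1/config$sim_dt`)
#' @param seed integer seed
#' @param direction hierarchy direction
#' @param priors,config model priors and configuration
#' @param linear integrate the linearized dynamics (TRUE) or the full
#'   sigmoid nonlinearity (FALSE)
#' @param epoch_length epoch length, seconds
#' @param input include the endogenous drive (FALSE gives zero input)
#' @param obs_noise add channel-specific and common observation noise
#' @param burn_in discarded initial transient, seconds
#' @param input_gain multiplier on the endogenous drive (used for
#'   linearization-limit checks)
#' @return an [epoched_ts()] object `[epoch, channel, sample]`
#' @export
simulate_timeseries <- function(theta = NULL, duration = 10, fs = 2000,
                                seed = 1, direction = "veridical",
                                priors = cmc_priors(), config = cmc_config(),
                                linear = TRUE, epoch_length = 0.5,
                                input = TRUE, obs_noise = TRUE,
                                burn_in = 2, input_gain = 1) {
  sys <- system_matrices(theta, direction, priors, config)
  stability_check(sys)
  phys <- sys$phys
  dt <- config$sim_dt
  fs_int <- 1 / dt
  keep <- fs_int / fs
  if (abs(keep - round(keep)) > 1e-9)
    stop("fs must divide 1/config$sim_dt (", fs_int, " Hz)")
  keep <- round(keep)
  nsteps <- round((duration + burn_in) * fs_int)
  set.seed(seed)
  drive <- matrix(0, nsteps, 2)
  if (input) {
    for (s in 1:2) {
      psd <- function(f) power_law_spectrum(f, phys[paste0("u_amp_", s)],
                                            phys[paste0("u_exp_", s)],
                                            config$noise_floor)
      drive[, s] <- input_gain * config$drive_scale *
        colored_noise(nsteps, fs_int, psd)
    }
  }
  Wint <- sys$net$intrinsic * config$coupling_scale
  Wext <- sys$net$extrinsic * config$coupling_scale
  v <- sim_cmc_cpp(Wint, Wext, sys$kappa, sys$rho, unname(phys["slope"]),
                   drive, c(0L, 4L), dt, round(config$delay / dt), linear)
  v <- v[seq(round(burn_in * fs_int) + 1, nsteps, by = keep), , drop = FALSE]
  n_out <- nrow(v)
  y <- matrix(0, n_out, 2)
  for (c in 1:2)
    y[, c] <- sys$gains[c] * drop(v[, (c - 1) * 4 + 1:4] %*% sys$jw)
  if (obs_noise) {
    common <- colored_noise(n_out, fs, function(f)
      power_law_spectrum(f, phys["c_amp"], phys["c_exp"], config$noise_floor))
    for (c in 1:2) {
      y[, c] <- y[, c] + common +
        colored_noise(n_out, fs, function(f)
          power_law_spectrum(f, phys[paste0("s_amp_", c)],
                             phys[paste0("s_exp_", c)], config$noise_floor))
    }
  }
  S <- round(epoch_length * fs)
  E <- floor(n_out / S)
  if (E < 1) stop("duration shorter than one epoch")
  arr <- array(0, c(E, 2, S))
  for (e in seq_len(E)) arr[e, , ] <- t(y[(e - 1) * S + seq_len(S), ])
  epoched_ts(arr, fs)
}
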