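#' Prior density over model parameters
#'
#' Returns the prior means and variances of the log-scaling parameterization
#' used throughout the package. Every biophysical quantity is stored as a
#' log-deviation `theta` around its prior mean, so that
#' `value = prior_mean * exp(theta)`; `theta = 0` reproduces the tabled prior
#' means exactly, and all physical magnitudes remain positive (connection
#' signs live in the fixed network structure, never in the parameters).
#'
#' The prior means are, per source: the ten intrinsic coupling gains
#' `G1..G10` (4, 4, 4, 4, 4, 2, 4, 4, 2, 1, arbitrary units), the four
#' synaptic time constants `T1..T4` (2, 2, 16, 28 ms for spiny stellate,
#' superficial pyramidal, inhibitory interneuron and deep pyramidal cells);
#' plus one forward extrinsic gain (superficial pyramidal origin), two
#' backward extrinsic gains (deep pyramidal origin, one per target
#' population), the sigmoid slope, per-channel electrode gains, the
#' observation weights of each population (0.2, 0.8, 0, 0.2), and the
#' amplitude/exponent coefficients of the endogenous-fluctuation,
#' channel-specific and channel-unspecific (common) noise spectra.
#'
#' @param intrinsic_var prior variance of log-scaling deviations on intrinsic
#'   and extrinsic coupling gains (default 1/8)
#' @param tc_var prior variance on time constants and sigmoid slope (1/16)
#' @param noise_var prior variance on spectral amplitude/exponent
#'   coefficients and electrode gains (1/8)
#' @param obs_var prior variance on the population observation weights (1/16)
#' @return an object of class `cmc_priors`: a list with named numeric vectors
#'   `mean` (physical prior means) and `var` (prior variances of the
#'   log-deviations; a variance of zero fixes the parameter)
#' @export
#' @examples
#' pr <- cmc_priors()
#' pr$mean[c("G1_1", "G6_1", "G10_1", "T4_1")]
cmc_priors <- function(intrinsic_var = 1/8, tc_var = 1/16,
                       noise_var = 1/8, obs_var = 1/16) {
  g_mean <- c(4, 4, 4, 4, 4, 2, 4, 4, 2, 1)
  t_mean <- c(2, 2, 16, 28) # milliseconds
  mean <- c()
  v <- c()
  for (s in 1:2) {
    gn <- paste0("G", 1:10, "_", s)
    tn <- paste0("T", 1:4, "_", s)
    mean[gn] <- g_mean
    v[gn] <- intrinsic_var
    mean[tn] <- t_mean
    v[tn] <- tc_var
  }
  mean["a_fwd"] <- 1
  mean["a_bwd_spc"] <- 0.5
  mean["a_bwd_ii"] <- 0.5
  v[c("a_fwd", "a_bwd_spc", "a_bwd_ii")] <- intrinsic_var
  mean["slope"] <- 2/3
  v["slope"] <- tc_var
  mean[c("gain_1", "gain_2")] <- 1
  v[c("gain_1", "gain_2")] <- noise_var
  mean[c("j_ss", "j_spc", "j_ii", "j_dpc")] <- c(0.2, 0.8, 0, 0.2)
  v[c("j_ss", "j_spc", "j_dpc")] <- obs_var
  v["j_ii"] <- 0 # multiplicative scaling cannot move a zero mean
  mean[c("u_amp_1", "u_amp_2")] <- 1
  mean[c("u_exp_1", "u_exp_2")] <- 1
  mean[c("s_amp_1", "s_amp_2")] <- 0.01
  mean[c("s_exp_1", "s_exp_2")] <- 1
  mean["c_amp"] <- 0.005
  mean["c_exp"] <- 1
  nn <- c("u_amp_1", "u_amp_2", "u_exp_1", "u_exp_2",
          "s_amp_1", "s_amp_2", "s_exp_1", "s_exp_2", "c_amp", "c_exp")
  v[nn] <- noise_var
  structure(list(mean = mean, var = v[names(mean)]), class = "cmc_priors")
}

#' Zero parameter vector (prior means)
#'
#' @param priors a `cmc_priors` object
#' @return named numeric vector of log-deviations, all zero
#' @export
cmc_theta <- function(priors = cmc_priors()) {
  setNames(numeric(length(priors$mean)), names(priors$mean))
}

# Physical parameter values from log-deviations.
theta_to_phys <- function(theta, priors = cmc_priors()) {
  th <- cmc_theta(priors)
  if (!is.null(names(theta))) {
    bad <- setdiff(names(theta), names(th))
    if (length(bad)) stop("unknown parameter names: ", paste(bad, collapse = ", "))
    th[names(theta)] <- theta
  } else {
    stopifnot(length(theta) == length(th))
    th[] <- theta
  }
  priors$mean * exp(th)
}

#' Model configuration
#'
#' Structural constants and algorithm settings that are not estimated. These
#' are the package's fixed conventions: the connection-strength scale that
#' converts the dimensionless tabled coupling gains into synaptic drive, the
#' endogenous drive amplitude scale (chosen so prior-mean channel autospectra
#' have average power of order one over 1-100 Hz), the extrinsic conduction
#' delay (applied as a phase factor in the frequency domain), the white
#' spectral floor added to every parameterized spectrum, the default
#' frequency grid and band definitions, the noise log-precision hyperprior,
#' and the variational-Laplace settings.
#'
#' @param coupling_scale fixed multiplier on all (intrinsic and extrinsic)
#'   connection weights, dimensionless
#' @param drive_scale fixed amplitude of the endogenous drive entering the
#'   spiny stellate populations
#' @param delay extrinsic conduction delay, seconds
#' @param noise_floor white floor added to every spectral density
#' @param freq default frequency grid, Hz (strictly increasing, positive)
#' @param bands named list of frequency intervals, Hz
#' @param hyper_mean,hyper_var Gaussian hyperprior on the noise
#'   log-precisions
#' @param max_iter,tol variational-Laplace iteration cap and free-energy
#'   convergence tolerance
#' @param fd_step central finite-difference step on log-deviations
#' @param sim_dt Euler-Maruyama integration step for time-domain
#'   simulation, seconds
#' @return a list of class `cmc_config`
#' @export
cmc_config <- function(coupling_scale = 1200, drive_scale = 12800,
                       delay = 0.016, noise_floor = 1e-6,
                       freq = 1:100,
                       bands = list(alpha = c(8, 12), beta = c(13, 30),
                                    gamma = c(40, 90)),
                       hyper_mean = 6, hyper_var = 1/128,
                       max_iter = 128, tol = 1e-2, fd_step = 1e-3,
                       sim_dt = 5e-4) {
  stopifnot(all(freq > 0), !is.unsorted(freq, strictly = TRUE),
            coupling_scale > 0, drive_scale > 0, delay >= 0)
  structure(list(coupling_scale = coupling_scale, drive_scale = drive_scale,
                 delay = delay, noise_floor = noise_floor, freq = freq,
                 bands = bands, hyper_mean = hyper_mean, hyper_var = hyper_var,
                 max_iter = max_iter, tol = tol, fd_step = fd_step,
                 sim_dt = sim_dt),
            class = "cmc_config")
}
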