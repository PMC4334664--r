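# Linearized spectral forward model: fixed point, transfer functions,
# predicted complex cross-spectral densities.

# Assemble the linear-system matrices at a parameter point.
system_matrices <- function(theta = NULL, direction = "veridical",
                            priors = cmc_priors(), config = cmc_config()) {
  phys <- theta_to_phys(if (is.null(theta)) cmc_theta(priors) else theta, priors)
  net <- build_network(theta, direction, priors)
  tc <- phys[paste0("T", rep(1:4, 2), "_", rep(1:2, each = 4))] / 1000
  if (any(tc <= 0)) stop("nonpositive time constant")
  kappa <- unname(1 / tc)
  rho <- unname(phys["slope"]) / 4
  Wint <- net$intrinsic * config$coupling_scale
  Wext <- net$extrinsic * config$coupling_scale
  K <- diag(kappa)
  Z <- matrix(0, 8, 8)
  J0 <- rbind(cbind(Z, diag(8)),
              cbind(K %*% Wint * rho - diag(kappa^2), -2 * K))
  Jext <- rbind(cbind(Z, Z), cbind(K %*% Wext * rho, Z))
  B <- matrix(0, 16, 2)
  B[8 + 1, 1] <- kappa[1] * config$drive_scale
  B[8 + 5, 2] <- kappa[5] * config$drive_scale
  jw <- unname(phys[c("j_ss", "j_spc", "j_ii", "j_dpc")])
  gains <- unname(phys[c("gain_1", "gain_2")])
  M <- rbind(c(gains[1] * jw, 0, 0, 0, 0),
             c(0, 0, 0, 0, gains[2] * jw))
  list(phys = phys, kappa = kappa, rho = rho, J0 = J0, Jext = Jext,
       B = B, M = M, jw = jw, gains = gains, net = net)
}

# Spectral density with a low-frequency plateau below 1 Hz and white floor.
power_law_spectrum <- function(f, amp, expn, floor = 1e-6) {
  amp * pmax(f, 1)^(-expn) + floor
}

stability_check <- function(sys, action = c("stop", "logical")) {
  action <- match.arg(action)
  ev <- eigen(sys$J0, only.values = TRUE)$values
  ok <- max(Re(ev)) < 0
  if (action == "logical") return(ok)
  if (!ok) {
    stop(structure(class = c("cmc_unstable", "error", "condition"),
                   list(message = sprintf(
                     "unstable linearization (max real eigenvalue %.3g >= 0)",
                     max(Re(ev))), call = sys.call(-1))))
  }
  invisible(ok)
}

#' Find the fixed point of the network dynamics
#'
#' With the centered sigmoid the origin is a fixed point for zero input;
#' this verifies the residual derivative norm and (defensively) applies
#' Newton iterations should the residual ever exceed the tolerance.
#'
#' @inheritParams state_derivatives
#' @param tol residual norm tolerance
#' @param max_iter Newton iteration budget
#' @return numeric state vector (length 16) with zero derivative
#' @export
find_fixed_point <- function(theta = NULL, direction = "veridical",
                             priors = cmc_priors(), config = cmc_config(),
                             tol = 1e-9, max_iter = 64) {
  x <- numeric(16)
  f <- state_derivatives(x, theta, c(0, 0), direction, priors, config)
  it <- 0
  while (sqrt(sum(f^2)) >= tol && it < max_iter) {
    sys <- system_matrices(theta, direction, priors, config)
    J <- sys$J0 + sys$Jext
    x <- x - solve(J, f)
    f <- state_derivatives(x, theta, c(0, 0), direction, priors, config)
    it <- it + 1
  }
  if (sqrt(sum(f^2)) >= tol)
    stop("no fixed point found within iteration budget")
  x
}

#' Frequency-resolved transfer functions
#'
#' Linearizes the network at its fixed point and returns the complex gain
#' from the endogenous input of each source to the depolarization of every
#' population, `T(w) = L (iwI - J(w))^{-1} B`, where the Jacobian carries
#' the extrinsic conduction delay as a frequency-domain phase factor.
#' Cross-source entries quantify directed spectral transfer and vanish
#' identically when the extrinsic gains are zero.
#'
#' @inheritParams state_derivatives
#' @param freq frequency grid in Hz (default from `config`)
#' @return object of class `cmc_tf`: list with complex array `tf`
#'   `[population-state (8), input source (2), frequency]`, the grid, and
#'   the direction
#' @export
transfer_functions <- function(theta = NULL, freq = NULL,
                               direction = "veridical",
                               priors = cmc_priors(), config = cmc_config()) {
  if (is.null(freq)) freq <- config$freq
  sys <- system_matrices(theta, direction, priors, config)
  stability_check(sys)
  tf <- tf_solve_cpp(sys$J0, sys$Jext, sys$B, 2 * pi * freq, config$delay, 8L)
  labs <- paste(rep(CMC_POPULATIONS, 2), rep(1:2, each = 4), sep = "_")
  dimnames(tf) <- list(labs, c("input_1", "input_2"), NULL)
  structure(list(tf = tf, freq = freq, direction = direction, sys = sys),
            class = "cmc_tf")
}

# Channel CSD from transfer functions, an observation matrix (rows =
# channels over the 8 depolarizations) and per-source input spectra
# (2 x F matrix). Returns complex array [F, C, C].
csd_from_tf <- function(tf, L, Gu) {
  nf <- dim(tf$tf)[3]
  C <- nrow(L)
  MT <- array(0i, c(C, 2, nf))
  for (k in seq_len(nf)) MT[, , k] <- L %*% tf$tf[, , k]
  G <- array(0i, c(nf, C, C))
  for (i in seq_len(C)) for (j in seq_len(C)) {
    acc <- complex(real = numeric(nf))
    for (s in 1:2) acc <- acc + MT[i, s, ] * Conj(MT[j, s, ]) * Gu[s, ]
    G[, i, j] <- acc
  }
  G
}

#' Predicted cross-spectral density at the channels
#'
#' Evaluates the generative spectral model
#' `G_y(w) = M T(w) G_u(w) T(w)^H M^H + G_s(w) + G_c(w)`: the endogenous
#' fluctuation spectra of each source are passed through the linearized
#' transfer functions and the observation mapping (electrode gain times
#' population contribution weights), then channel-specific noise is added to
#' the diagonal and channel-unspecific (common) noise to every entry. The
#' result is Hermitian with real nonnegative diagonal at every frequency.
#'
#' @inheritParams transfer_functions
#' @param noise include the modeled channel-specific and common noise
#' @param unit_gain replace the electrode gains by one (used for noise-free
#'   reconstructions)
#' @return a [csd_data()] object over two channels
#' @export
predict_csd <- function(theta = NULL, freq = NULL, direction = "veridical",
                        priors = cmc_priors(), config = cmc_config(),
                        noise = TRUE, unit_gain = FALSE) {
  if (is.null(freq)) freq <- config$freq
  tf <- transfer_functions(theta, freq, direction, priors, config)
  sys <- tf$sys
  phys <- sys$phys
  L <- sys$M
  if (unit_gain) L <- rbind(c(sys$jw, rep(0, 4)), c(rep(0, 4), sys$jw))
  Gu <- rbind(power_law_spectrum(freq, phys["u_amp_1"], phys["u_exp_1"],
                                 config$noise_floor),
              power_law_spectrum(freq, phys["u_amp_2"], phys["u_exp_2"],
                                 config$noise_floor))
  G <- csd_from_tf(tf, L, Gu)
  if (noise) {
    for (c in 1:2) {
      Gs <- power_law_spectrum(freq, phys[paste0("s_amp_", c)],
                               phys[paste0("s_exp_", c)], config$noise_floor)
      if (any(Gs <= 0)) stop("nonpositive noise spectrum")
      G[, c, c] <- G[, c, c] + Gs
    }
    Gc <- power_law_spectrum(freq, phys["c_amp"], phys["c_exp"],
                             config$noise_floor)
    for (i in 1:2) for (j in 1:2) G[, i, j] <- G[, i, j] + Gc
  }
  # enforce exact Hermitian structure against roundoff
  for (c in 1:2) G[, c, c] <- complex(real = Re(G[, c, c]))
  G[, 2, 1] <- Conj(G[, 1, 2])
  csd_data(G, freq, channels = c("ch1", "ch2"))
}

#' Population-specific cross-spectral density
#'
#' Noise-free CSD computed with an indicator observation vector on the
#' requested population(s) of one source (unit gain, zero noise). Passing
#' several populations returns their joint CSD including cross-population
#' terms, so that the weighted sum over populations with the observation
#' weights reproduces the noise-free channel spectrum.
#'
#' @inheritParams transfer_functions
#' @param population character vector from `SS`, `SPC`, `II`, `DPC`
#' @param source source index (1 = lower, 2 = higher)
#' @return a [csd_data()] object over the requested populations
#' @export
population_csd <- function(theta = NULL, freq = NULL, population = "SPC",
                           source = 1, direction = "veridical",
                           priors = cmc_priors(), config = cmc_config()) {
  stopifnot(all(population %in% CMC_POPULATIONS), source %in% 1:2)
  if (is.null(freq)) freq <- config$freq
  tf <- transfer_functions(theta, freq, direction, priors, config)
  phys <- tf$sys$phys
  L <- matrix(0, length(population), 8)
  for (k in seq_along(population))
    L[k, (source - 1) * 4 + match(population[k], CMC_POPULATIONS)] <- 1
  Gu <- rbind(power_law_spectrum(freq, phys["u_amp_1"], phys["u_exp_1"],
                                 config$noise_floor),
              power_law_spectrum(freq, phys["u_amp_2"], phys["u_exp_2"],
                                 config$noise_floor))
  G <- csd_from_tf(tf, L, Gu)
  for (c in seq_along(population))
    G[, c, c] <- complex(real = Re(G[, c, c]))
  csd_data(G, freq, channels = paste(population, source, sep = "_"))
}

#' Noise-free reconstruction from a model fit
#'
#' Predicted CSD at the posterior means with the modeled channel-specific
#' and common noise removed and the electrode gains set to unity; the
#' spectra one would have observed in the absence of measurement noise.
#'
#' @param fit a converged [fit_csd()] result
#' @param freq frequency grid (default: the grid the fit used)
#' @return a [csd_data()] object
#' @export
denoised_csd <- function(fit, freq = NULL) {
  stopifnot(inherits(fit, "cmc_fit"))
  if (!isTRUE(fit$converged)) stop("unconverged fit")
  if (is.null(freq)) freq <- fit$freq
  predict_csd(fit$mu, freq, fit$direction, fit$priors, fit$config,
              noise = FALSE, unit_gain = TRUE)
}

#' Complex cross-spectral data container
#'
#' @param csd complex array `[frequency, channel, channel]`, Hermitian at
#'   every frequency with real nonnegative diagonal
#' @param freq frequency grid, Hz
#' @param channels channel labels
#' @param n_epochs,fs optional metadata (epoch count, sampling rate)
#' @return object of class `csd_data`
#' @export
csd_data <- function(csd, freq, channels = NULL, n_epochs = NA_integer_,
                     fs = NA_real_) {
  stopifnot(length(dim(csd)) == 3, dim(csd)[1] == length(freq),
            dim(csd)[2] == dim(csd)[3])
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(csd)[2]))
  structure(list(csd = csd, freq = freq, channels = channels,
                 n_epochs = n_epochs, fs = fs),
            class = "csd_data")
}

#' @export
print.csd_data <- function(x, ...) {
  cat(sprintf("<csd_data> %d channels x %d frequencies (%.4g-%.4g Hz)\n",
              length(x$channels), length(x$freq), min(x$freq), max(x$freq)))
  if (!is.na(x$n_epochs)) cat(sprintf("  estimated from %d epochs at %g Hz\n",
                                      x$n_epochs, x$fs))
  invisible(x)
}

# Hermitian check with tolerance (relative to the typical magnitude).
# require_psd additionally demands a nonnegative diagonal (appropriate for
# model predictions; noisy observed features may dip below zero).
csd_is_hermitian <- function(x, tol = 1e-8, require_psd = TRUE) {
  sc <- max(abs(x$csd), 1e-300)
  for (k in seq_along(x$freq)) {
    m <- x$csd[k, , ]
    if (max(abs(m - Conj(t(m)))) > tol * sc) return(FALSE)
    if (any(abs(Im(diag(m))) > tol * sc)) return(FALSE)
    if (require_psd && any(Re(diag(m)) < -tol * sc)) return(FALSE)
  }
  TRUE
}
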