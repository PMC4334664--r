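test_that("the fixed point is the origin with vanishing residual", {
  for (seed in 1:5) {
    th <- sample_prior(seed = seed)
    x <- find_fixed_point(th)
    expect_identical(x, numeric(16))
    f <- state_derivatives(x, th)
    expect_lt(sqrt(sum(f^2)), 1e-9)
  }
})

test_that("transfer magnitudes match the DFT of the integrated impulse response", {
  # independent oracle: step the linearized system with the exact matrix
  # exponential and Fourier-transform the impulse response
  cf <- cmc_config(delay = 0) # the integration oracle carries no delay
  freq <- seq(5, 80, 5)
  tf <- transfer_functions(NULL, freq, config = cf)
  sys <- tf$sys
  J <- sys$J0 + sys$Jext
  dt <- 2e-5
  n <- round(1.5 / dt)
  E <- as.matrix(Matrix::expm(J * dt))
  for (src in 1:2) {
    x <- sys$B[, src]
    h <- matrix(0, n, 8)
    for (t in seq_len(n)) {
      x <- E %*% x
      h[t, ] <- x[1:8]
    }
    tt <- seq_len(n) * dt
    for (k in seq_along(freq)) {
      H <- colSums(h * exp(-2i * pi * freq[k] * tt)) * dt
      err <- abs(abs(H) - abs(tf$tf[, src, k])) / max(abs(tf$tf[, src, k]))
      expect_lt(max(err), 0.01)
    }
  }
})

test_that("prior transfer functions peak in gamma forward and below 30 Hz backward", {
  freq <- 1:100
  tf <- transfer_functions(NULL, freq)
  spc_v1 <- abs(tf$tf["SPC_1", 1, ])
  dpc_v4 <- abs(tf$tf["DPC_2", 2, ])
  expect_gt(freq[which.max(spc_v1)], 30)
  expect_lt(freq[which.max(dpc_v4)], 30)
})

test_that("predicted CSDs are Hermitian with nonnegative diagonal over prior draws", {
  for (seed in 1:25) {
    th <- sample_prior(seed = seed)
    g <- predict_csd(th, tiny_grid)
    expect_true(spectraldcm:::csd_is_hermitian(g, tol = 1e-8))
  }
})

test_that("unstable parameterizations are rejected with a typed condition", {
  th <- cmc_theta()
  th[c("G1_1", "G4_1", "G7_1", "G10_1")] <- -6 # remove self-inhibition
  th["G5_1"] <- 3
  sys <- spectraldcm:::system_matrices(th)
  skip_if(spectraldcm:::stability_check(sys, "logical"),
          "could not construct an unstable draw")
  expect_error(transfer_functions(th, tiny_grid), class = "cmc_unstable")
})

test_that("vanishing electrode gains leave only the noise spectrum", {
  th <- cmc_theta()
  th[c("gain_1", "gain_2")] <- -1e3
  g <- predict_csd(th, tiny_grid)
  phys <- spectraldcm:::theta_to_phys(th)
  cf <- cmc_config()
  gs <- spectraldcm:::power_law_spectrum(tiny_grid, phys["s_amp_1"],
                                         phys["s_exp_1"], cf$noise_floor)
  gc <- spectraldcm:::power_law_spectrum(tiny_grid, phys["c_amp"],
                                         phys["c_exp"], cf$noise_floor)
  expect_equal(Re(g$csd[, 1, 1]), unname(gs + gc), tolerance = 1e-10)
  expect_equal(Re(g$csd[, 1, 2]), unname(gc), tolerance = 1e-10)
  expect_equal(Im(g$csd[, 1, 2]), numeric(length(tiny_grid)), tolerance = 1e-12)
})

test_that("an isolated input population reproduces the second-order filter response", {
  th <- isolated_theta()
  freq <- tiny_grid
  p <- population_csd(th, freq, "SS", 1)
  cf <- cmc_config()
  phys <- spectraldcm:::theta_to_phys(th)
  kap <- 1000 / unname(phys["T1_1"])
  Gu <- spectraldcm:::power_law_spectrum(freq, phys["u_amp_1"],
                                         phys["u_exp_1"], cf$noise_floor)
  Hmag2 <- abs(kap * cf$drive_scale / (2i * pi * freq + kap)^2)^2
  expect_equal(Re(p$csd[, 1, 1]), unname(Hmag2 * Gu), tolerance = 1e-8)
})

test_that("population CSDs are bilinear: weighted sum equals the channel CSD", {
  th <- sample_prior(seed = 3)
  freq <- tiny_grid
  full <- population_csd(th, freq, c("SS", "SPC", "II", "DPC"), source = 1)
  phys <- spectraldcm:::theta_to_phys(th)
  jw <- phys[c("j_ss", "j_spc", "j_ii", "j_dpc")]
  chan <- predict_csd(th, freq, noise = FALSE, unit_gain = TRUE)
  mixed <- vapply(seq_along(freq), function(k)
    Re(drop(jw %*% full$csd[k, , ] %*% jw)), numeric(1))
  expect_equal(mixed, Re(chan$csd[, 1, 1]), tolerance = 1e-8)
})

test_that("source autospectra scale linearly with input amplitude", {
  th <- zero_extrinsic_theta()
  th2 <- th
  th2["u_amp_1"] <- log(3)
  base <- population_csd(th, tiny_grid, "SPC", 1)
  scaled <- population_csd(th2, tiny_grid, "SPC", 1)
  # with extrinsic coupling removed, source 1 sees only its own input,
  # so the scaling is exact up to the additive white floor
  expect_equal(Re(scaled$csd[, 1, 1]), 3 * Re(base$csd[, 1, 1]),
               tolerance = 1e-4)
  # whole-system linearity: scaling both inputs scales the channel CSD
  thc <- cmc_theta(); thc[c("u_amp_1", "u_amp_2")] <- log(2)
  g1 <- predict_csd(NULL, tiny_grid, noise = FALSE)
  g2 <- predict_csd(thc, tiny_grid, noise = FALSE)
  # exact up to the additive white spectral floor, which does not scale
  expect_equal(g2$csd, 2 * g1$csd, tolerance = 1e-4)
})

test_that("prior laminar asymmetry: superficial gamma, deep alpha/beta", {
  freq <- 1:100
  spc <- Re(population_csd(NULL, freq, "SPC", 1)$csd[, 1, 1])
  dpc <- Re(population_csd(NULL, freq, "DPC", 1)$csd[, 1, 1])
  expect_gt(band_power(spc, freq, c(40, 90)), band_power(dpc, freq, c(40, 90)))
  expect_gt(band_power(dpc, freq, c(8, 30)), band_power(spc, freq, c(8, 30)))
})

test_that("denoising removes positive noise power and preserves structure", {
  fit <- quick_fit()
  den <- denoised_csd(fit)
  pred <- predict_csd(fit$mu, fit$freq, fit$direction, fit$priors, fit$config,
                      noise = TRUE, unit_gain = TRUE)
  expect_true(all(Re(den$csd[, 1, 1]) <= Re(pred$csd[, 1, 1])))
  expect_true(all(Re(den$csd[, 2, 2]) <= Re(pred$csd[, 2, 2])))
  expect_true(spectraldcm:::csd_is_hermitian(den))
  bad <- fit
  bad$converged <- FALSE
  expect_error(denoised_csd(bad), "unconverged")
})
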