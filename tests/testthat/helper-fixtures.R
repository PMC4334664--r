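# Shared fixtures: coarse grids and quick variational-Laplace settings used
# across the suite to keep runtimes at desk scale.

coarse_grid <- seq(4, 96, 4)
tiny_grid <- seq(8, 88, 8)

# parameters with extrinsic coupling numerically zeroed (exp(-1e3) == 0)
zero_extrinsic_theta <- function() {
  th <- cmc_theta()
  th[c("a_fwd", "a_bwd_spc", "a_bwd_ii")] <- -1e3
  th
}

# parameters with all couplings zeroed: isolated populations
isolated_theta <- function() {
  th <- zero_extrinsic_theta()
  th[grep("^G", names(th))] <- -1e3
  th
}

# a quick converged fit on noise-free data at the prior means
quick_fit <- function(grid = tiny_grid, direction = "veridical") {
  d <- generate_dataset(NULL, grid, log_precision = 31,
                        direction = direction)
  fit_csd(d$csd, direction)
}
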