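# spectraldcm

Dynamic causal modeling of complex cross-spectral densities with
four-population canonical microcircuits.

## What problem this solves

Invasive recordings from two cortical areas (say V1 and V4) yield complex
cross-spectral densities: frequency-resolved auto- and cross-spectra that
mix the underlying neuronal dynamics with channel-specific and common
measurement noise. Questions such as *which area is hierarchically higher*,
*which frequencies carry forward versus backward influences*, and *what
would the spectra look like without measurement noise* cannot be answered
from the raw spectra alone. This package answers them with a biophysical
generative model and Bayesian model comparison, for researchers working on
directed cortical connectivity and oscillatory communication.

Each cortical source is a canonical microcircuit of four neural masses —
spiny stellate cells (SS), superficial pyramidal cells (SPC), inhibitory
interneurons (II), and deep pyramidal cells (DPC) — with fixed connection
signs (one excitatory and one inhibitory direction in every reciprocal
pair, inhibitory self-connections) and second-order synaptic dynamics
$\ddot v = \kappa u - 2\kappa\dot v - \kappa^2 v$ per population. Forward
projections originate in SPC and excite the granular layer of the higher
source; backward projections originate in DPC and inhibit SPC and II of
the lower source. Linearization at the fixed point yields transfer
functions $T(\omega) = L(i\omega I - J(\omega))^{-1}B$ and a predicted
channel CSD

$$G_y(\omega) = M\,T(\omega)\,G_u(\omega)\,T(\omega)^{\mathsf H}M^{\mathsf H}
 + G_s(\omega) + G_c(\omega),$$

which is fit to data by variational Laplace (Gaussian posterior,
free-energy ascent). Free energy differences — and a reduced,
accuracy-based log evidence for channel pairs — compare the veridical
hierarchy against the reversed one; the fitted model then gives
population-resolved spectra, denoised spectra, and directed transfer
functions.

## Worked example

```r
library(spectraldcm)

# 1. Spectra of the two pyramidal populations under the prior model
freq <- 1:100
spc <- Re(population_csd(NULL, freq, "SPC", 1)$csd[, 1, 1])
dpc <- Re(population_csd(NULL, freq, "DPC", 1)$csd[, 1, 1])
band_power(spc, freq, c(40, 90)) / band_power(dpc, freq, c(40, 90))
#> [1] 24.17668
band_power(dpc, freq, c(8, 30)) / band_power(spc, freq, c(8, 30))
#> [1] 7.789804

# 2. A synthetic two-source dataset and its inversion under both hierarchies
theta <- sample_prior(seed = 101)
d <- generate_dataset(theta, seq(4, 96, 4), log_precision = 7, seed = 201)
cmp <- compare_models(d$csd)
cmp
#>   direction          F  accuracy complexity reduced_F converged
#> 1 veridical   68.44202  144.1246   75.68261  120.9806      TRUE
#> 2  reversed -699.69625 -225.4240  474.27229 -257.0006      TRUE
#> dF (veridical - reversed) = 768.138 -> selected: veridical

# 3. Directed spectral asymmetry of the generative model
asymmetry_report(cmc_theta())[, c("peak_forward_hz", "peak_backward_hz",
                                  "asymmetry_index")]
#>   peak_forward_hz peak_backward_hz asymmetry_index
#> 1              48               18       0.6859112
```

The superficial pyramidal population carries about 24 times more gamma-band
(40–90 Hz) power than the deep pyramidal population, while the deep
population carries about 8 times more alpha/beta (8–30 Hz) power — the
laminar asymmetry the model's priors are built to express. Model comparison
recovers the generative hierarchy with a free-energy difference of ~768
(odds overwhelmingly in favor), and the transfer functions show forward
signalling peaking in the gamma band (48 Hz) and backward signalling in the
beta band (18 Hz), summarized by a positive gamma-fraction asymmetry index.

## Command line

A thin CLI wraps the package functions:

```sh
Rscript inst/cli/spectraldcm.R simulate --seed 3 --out sim
Rscript inst/cli/spectraldcm.R compare --in sim_csd.csv --out sim
Rscript inst/cli/spectraldcm.R validate --n-datasets 15 --log-precision 7
```

## Layout

- `R/` — model core, spectral forward model, variational Laplace
  inversion, multitaper CSD estimation, synthetic data, reporting, I/O
- `src/` — Armadillo kernels: frequency-domain transfer-function solves
  and the stochastic Heun integrator with conduction-delay buffer
- `vignettes/spectral-dcm-methods.Rmd` — the model, priors, inversion
  scheme, numerical choices, and limitations
- `tests/testthat/` — unit, property, and end-to-end acceptance tests
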