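---
title: "Modeling directed cortical coupling from cross-spectral densities"
author: "spectraldcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling directed cortical coupling from cross-spectral densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectraldcm)
```

## The model

`spectraldcm` implements a generative model of complex cross-spectral
densities (CSDs) recorded from two hierarchically coupled cortical sources,
and its Bayesian inversion. Each source is a canonical microcircuit of four
neural masses: spiny stellate input cells (SS, granular layer), superficial
pyramidal cells (SPC), inhibitory interneurons (II), and deep pyramidal
cells (DPC). Superficial pyramidal cells originate forward (ascending)
projections that excite the granular layer of the higher source; deep
pyramidal cells originate backward (descending) projections that inhibit
the superficial pyramidal cells and interneurons of the lower source.

Each population carries a post-synaptic depolarization $v$ obeying
second-order synaptic convolution dynamics with rate constant
$\kappa = 1/T$,

$$\ddot v = \kappa u - 2\kappa \dot v - \kappa^2 v,$$

whose impulse response is the alpha kernel $\kappa^2 t e^{-\kappa t}$
peaking at $t = T$. The synaptic drive $u$ is the signed, weighted sum of
presynaptic firing rates through the fixed connectivity, plus endogenous
fluctuations entering the spiny stellate cells. Firing rates come from a
centered logistic sigmoid $S(v) = 1/(1+e^{-sv}) - 1/2$, so the origin is
a fixed point and the linearized synaptic gain is $s/4$.

Every reciprocally connected population pair carries one excitatory and one
inhibitory direction, and all self-connections are inhibitory. This
anti-symmetry balances excitation and inhibition and guarantees a
fixed-point attractor, which is what licenses the linear (local stability)
analysis behind the spectral predictions: linearizing at the fixed point
gives frequency-resolved transfer functions
$T(\omega) = L\,(i\omega I - J(\omega))^{-1} B$ from the endogenous input
of each source to the depolarization of every population, and the predicted
channel CSD is

$$G_y(\omega) = M\,T(\omega)\,G_u(\omega)\,T(\omega)^{\mathsf H} M^{\mathsf H}
  + G_s(\omega) + G_c(\omega),$$

with $M$ the observation mapping (electrode gain times per-population
contribution weights), $G_u$ the diagonal endogenous-fluctuation spectra,
$G_s$ channel-specific noise on the diagonal, and $G_c$ a common (rank-one,
all-ones) noise term shared by all channels.

## Parameters, units, and priors

All biophysical quantities are parameterized as log-scaling deviations
$\vartheta$ around prior means, value $= \bar\pi e^{\vartheta}$, so
$\vartheta = 0$ reproduces the prior means exactly and positivity is
automatic; connection signs live in the fixed structure, never in the
parameters. The prior means are the tabled values: intrinsic gains
$(4,4,4,4,4,2,4,4,2,1)$ for the ten connections (SS$\to$SS, SPC$\to$SS,
II$\to$SS, II$\to$II, SS$\to$II, DPC$\to$II, SPC$\to$SPC, SS$\to$SPC,
II$\to$DPC, DPC$\to$DPC), time constants $(2, 2, 16, 28)$ ms for
(SS, SPC, II, DPC), and observation weights $(0.2, 0.8, 0, 0.2)$ — the
superficial pyramidal cells dominate the recorded signal. Prior variances
default to $1/8$ on coupling gains, electrode gains and spectral
coefficients, and $1/16$ on time constants, the sigmoid slope and the
observation weights; the interneuron weight has prior mean zero, which a
multiplicative parameterization keeps at exactly zero, so it is fixed.

Several constants are not printed anywhere and are the package's own
choices, fixed once in `cmc_config()`:

* **Sigmoid slope** $s = 2/3$ (prior mean), giving linearized gain
  $1/6$ — the logistic form itself is a modeling choice; only "a sigmoid"
  is prescribed by the model family.
* **Coupling scale** 1200. The tabled gains are dimensionless; multiplied
  by the sigmoid gain alone they are far too weak to produce any
  resonance (every transfer function would be low-pass). A fixed
  connection-strength scale is therefore part of the amplitude convention
  of this model family. The value 1200 places the prior-mean resonances
  where the model is designed to put them: the input$\to$SPC (forward
  origin) transfer peaks near 48 Hz (gamma) and the input$\to$DPC
  (backward origin) transfer near 18 Hz (beta), and prior spectra give
  superficial cells more gamma power and deep cells more alpha/beta power.
* **Drive scale** 12800, the amplitude of endogenous input entering the
  granular layer. This sets the otherwise arbitrary voltage/power units so
  that prior-mean channel autospectra have average power of order one over
  1–100 Hz, which keeps the noise-precision hyperprior (below) on a
  meaningful scale.
* **Extrinsic gain prior means**: forward 1.0, backward 0.5 per target.
* **Conduction delay** 16 ms on extrinsic connections, applied exactly in
  the frequency domain as a phase factor $e^{-i\omega\Delta}$ on the
  extrinsic Jacobian block (no delay-differential integration is needed
  for a linear system). Intrinsic connections carry no delay.
* **Spectral forms**: endogenous fluctuations and both noise components
  are power laws $\alpha f^{-\beta}$ with a low-frequency plateau below
  1 Hz and a white floor of $10^{-6}$ for numerical stability. Amplitudes
  multiply spectral density directly (power units). Prior means:
  fluctuation amplitude 1 and exponent 1 per source; channel-specific
  noise amplitude 0.01; common noise amplitude 0.005; exponents 1.
* **Frequency grid**: 1–100 Hz at 1 Hz by default; the fitted range is
  configurable because no canonical grid exists for this model class.

## Inversion

`fit_csd()` reduces the complex CSD to real features — real and imaginary
parts of the upper triangle across frequencies, in a documented
deterministic order — and ascends a variational free energy
$F = \text{accuracy} - \text{complexity}$ by Gauss–Newton updates with
Levenberg–Marquardt damping. Steps that lower $F$ are rejected and retried
with stronger damping, so the accepted trace is nondecreasing by
construction; convergence is declared when $\Delta F$ falls below `tol`
(default $10^{-2}$) with an iteration cap of 128. Gradients are central
finite differences in the log-scaling parameters (step $10^{-3}$):
robustness was preferred over speed at the problem sizes this package
targets. Parameter draws or proposals with an unstable linearization are
rejected by backtracking. The posterior is the Gaussian (Laplace)
approximation $N(\mu, \Sigma)$ with
$\Sigma = (J^{\mathsf T}\Pi J + C_p^{-1})^{-1}$.

The noise precision $\Pi$ is diagonal with one log-precision per channel
pair (auto 1, cross 1–2, auto 2), updated by a Newton M-step under a
Gaussian hyperprior of mean 6 and variance $1/128$. This deliberately
precise hyperprior mirrors the practice of the model family; a consequence
worth knowing is that posterior credible intervals are then insensitive to
the realized noise level, because the estimated precision barely moves.
(The package's test suite demonstrates the expected widening of credible
intervals with noise under a loosened hyperprior, `hyper_var = 1`.) The
$-\tfrac n2\ln 2\pi$ constant is included in $F$ but excluded from the
reduced evidence below, where it cancels between models of equal dimension.

Model comparison between the veridical hierarchy (forward from the lower
source) and the reversed one uses the free energy, and additionally the
*reduced log evidence* on a channel pair,
$F_{ij} = -\tfrac12\varepsilon^{\mathsf T}\Pi\varepsilon
+ \tfrac12\ln|\Pi|$, evaluated at the posterior mean on that pair's
features. It is appropriate when the competing models share parameter
count and priors, so their complexities are equivalent; a difference of 3
corresponds to odds of about 20:1. Evidence pools over independent
datasets by summation. Ties ($|\Delta F| < 10^{-6}$) are reported as
indistinguishable.

## Synthetic data and what it does (not) establish

`sample_prior()` draws stable parameter sets; `generate_dataset()` adds
complex Gaussian noise to the predicted CSD so that total signal variance
over total noise variance equals $e^\lambda$ at log precision $\lambda$,
allocated across frequencies proportionally to mean signal power
(log precisions $\ge 30$ are treated as exactly noiseless). Hermitian
structure is preserved. `simulate_timeseries()` integrates the linearized
(or, optionally, full nonlinear) stochastic dynamics with a stochastic
Heun scheme at 0.5 ms steps, a delay buffer for the extrinsic lag, and
colored drive generated by frequency-domain spectral shaping. A plain
forward Euler step at this step size systematically under-damps the gamma
resonance (the amplification factor $|1+\lambda\,dt|$ of the dominant
eigenvalue pair is visibly closer to one than $e^{\mathrm{Re}\lambda\,dt}$),
inflating peak power by tens of percent; the Heun step removes this bias at
unchanged cost, which is why it is the integrator here.

The simulator emulates the statistical structure the analysis assumes —
stationary Gaussian fluctuations with parameterized spectra passing through
a stable linear system, plus channel-specific and common observation noise.
It does not emulate nonstationarity, task structure, line noise, movement
artifacts, volume conduction, or the site-selection step of real
electrocorticography; passing the synthetic checks therefore validates the
estimator and the inversion machinery, not the model's adequacy for any
particular recording.

The generative parameters of the face-validity experiment are prior
samples: the original protocol used posterior estimates from fitted
empirical recordings, which are not available to this package.

## Desk-scale problem sizes

The package's own validation experiments are sized for a desktop run and
stated here as the package's reference conditions: the simulation oracle
uses a 600 s linearized simulation at 2000 Hz, 2 s epochs, and a 7-taper
multitaper estimate, with median relative error below 10% over 5–80 Hz;
face-validity model recovery uses five prior-sampled datasets at log
precision 7 on a 4–96 Hz grid at 4 Hz spacing, requiring at least four
correct selections (the 15-dataset variant of the original protocol is the
same code path via `inst/cli/spectraldcm.R validate --n-datasets 15`);
parameter recovery fits noise-free prior-mean data from ten jittered
starts; the end-to-end time-series check (simulate, estimate, fit both
hierarchies) uses three 120 s runs; and the precision-monotonicity check
uses five datasets per log-precision level in $\{1, 4, 7\}$.

## Numerical choices and degenerate inputs

* Stability is assessed on the delay-free Jacobian; the frequency-domain
  delay phase does not enter the eigenvalue check. Unstable
  parameterizations raise a typed condition (`cmc_unstable`) and are
  rejected during sampling and line search.
* The multitaper estimator uses DPSS (Slepian) tapers with time-bandwidth
  2 and 3 tapers by default, computed from the standard tridiagonal
  eigenproblem; above 1024 samples the tapers are spline-interpolated from
  1024 points and re-orthonormalized. Parametric (autoregressive)
  estimators were deliberately avoided for robustness on 0.5 s epochs.
* Zero-variance epochs are dropped (with a message) before z-scoring, and
  fewer than two surviving epochs is an error.
* Observed CSDs are required to be Hermitian but may carry small negative
  diagonal excursions (noise on spectral features); model predictions are
  required to be Hermitian with nonnegative diagonal.
* Model selection with $|\Delta F| < 10^{-6}$ is reported as
  indistinguishable rather than picking a winner.
* Serialization is plain text: CSV bundles for cross-spectral and epoched
  data, JSON for fits and comparisons.

## Known limitations

Two sources and one channel per source; no electromagnetic lead field (the
observation model is for invasive recordings with parameterized electrode
gains); single-dataset fits with offline pooling of evidence rather than
hierarchical group inversion; forward projections terminate only on the
granular layer; and the bilinear/condition-specific extensions of this
model family (induced responses, attention contrasts) are out of scope.

## A short session

```{r example, eval = FALSE}
library(spectraldcm)

# prior-mean spectra of the two pyramidal populations
freq <- 1:100
spc <- Re(population_csd(NULL, freq, "SPC", 1)$csd[, 1, 1])
dpc <- Re(population_csd(NULL, freq, "DPC", 1)$csd[, 1, 1])
band_power(spc, freq, c(40, 90)) / band_power(dpc, freq, c(40, 90))

# a synthetic dataset and its inversion under both hierarchies
theta <- sample_prior(seed = 101)
d <- generate_dataset(theta, seq(4, 96, 4), log_precision = 7, seed = 201)
cmp <- compare_models(d$csd)
cmp$selected
evidence_to_odds(cmp$dF)

# directed spectral asymmetry of the fitted model
asymmetry_report(cmp$fits$veridical)
```
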