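Package: spectraldcm
Title: Dynamic Causal Modeling of Cross-Spectral Densities with Canonical Microcircuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generative spectral model of hierarchically coupled cortical
    sources built from four-population canonical microcircuits (spiny stellate,
    superficial pyramidal, inhibitory interneuron, deep pyramidal), with
    variational Laplace inversion of complex cross-spectral densities,
    free-energy model comparison between candidate hierarchies, multitaper
    cross-spectral estimation from epoched local field potentials, synthetic
    data generation, and reconstruction of population-specific spectra and
    directed transfer functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
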