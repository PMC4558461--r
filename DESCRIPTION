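Package: seizuredcm
Title: Dynamic Causal Modelling of Focal Seizure Spectra with a Canonical
    Microcircuit Neural Mass Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks slow fluctuations in cortical excitatory and inhibitory
    synaptic gain across epileptic seizures recorded with EEG. Seizure
    recordings are windowed and reduced to autoregressive spectral densities;
    a four-population canonical-microcircuit neural mass model with conduction
    delays predicts those spectra through its linearised transfer functions,
    driven by power-law ("scale-free") endogenous input and observed through a
    pyramidal-cell mixture with power-law measurement noise. Slow parameter
    drift over seizure time-windows is expanded on a discrete cosine basis and
    the full windowed dataset is inverted at once by variational Laplace;
    competing hypotheses about which parameter groups change during seizures
    (inhibitory connectivity, excitatory connectivity, endogenous input) are
    scored by free-energy Bayesian model comparison. Includes a synthetic
    seizure generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
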