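Package: specdcm
Title: Dynamic Causal Modelling of Evoked and Induced Spectral Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a generic dynamic causal model that explains evoked and
    induced spectral responses of coupled neuronal sources simultaneously. The
    model is a bilinear state equation on frequency-mode amplitudes whose
    condition-specific coupling changes capture induced components over and
    above evoked ones. The package provides the time-frequency feature
    pipeline (Morlet transform, evoked/induced condition construction,
    baseline correction, SVD mode reduction), variational Laplace model
    inversion with free-energy model evidence, fixed- and random-effects
    Bayesian model selection with exceedance probabilities, group-level
    inference on modulation matrices (frequency-space smoothing and t-maps),
    and a synthetic-data module for identifiability studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
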