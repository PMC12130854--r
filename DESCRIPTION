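Package: powerlawcoding
Title: Fisher Information and Optimal Exponents for Power-Law Neural
    Population Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing power-law population codes: a stochastic
    encoding model in which Fourier receptive-field amplitudes decay as
    n^(-alpha/2) under shared input noise and independent neural noise,
    closed-form Fisher information of the code at finite and infinite
    population size, an energy-aware performance measure whose optimum
    lies at the critical exponent 1 + 2/D, a maximum-likelihood decoder
    for the circular stimulus built by numerical integration of the exact
    posterior, and empirical checks of the susceptibility-variance
    relationship and the power-law eigenspectrum. Experiment pipelines
    return tidy tibbles and serialize to CSV with JSON metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
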