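Package: pestkern
Title: Dispersal-Kernel Estimation and Spread Simulation for Forest Pests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits radially symmetric two-dimensional dispersal (redistribution)
    kernels to yearly gridded infestation records via a convolution likelihood,
    compares thin-tailed, fat-tailed and mixture kernel families, validates
    fitted models with true-positive rates, log-scale forecast correlations,
    nearest-parent distance analysis and distance-stratified log likelihoods,
    and simulates multi-year stochastic spread with prescribed yearly totals
    under a habitat mask. Includes a synthetic-data generator that emulates
    helicopter-survey infestation data so the whole pipeline is testable
    without restricted survey records.
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
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
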