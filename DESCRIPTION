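Package: senesim
Title: Individual-Based Simulation of Life-History and Aging Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, age-structured, individual-based simulation of the
    evolution of life-history traits and senescence. Heritable bit-string
    genomes encode evolvable age-specific survival, fertility and germline
    mutation rates; populations are subjected each step to configurable
    mortality processes (intrinsic, abiotic, infection, predation,
    starvation), reproduction with recombination, assortment and mutation,
    aging, and environmental drift. Includes recorders for demography,
    intrinsic versus observed life-history curves and site frequency
    spectra, a burn-in/comparative experiment harness, and a preset
    recreating a classical delayed-reproduction selection experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
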