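Package: isawtheta
Title: Exact Enumeration of Interacting Self-Avoiding Walks and the Theta
    Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact exhaustive enumeration of interacting self-avoiding walks
    (ISAW) on the simple cubic lattice, producing the exact density of states
    over contact number and squared end-to-end distance. Builds the partition
    function and end-to-end polynomials in the contact fugacity, solves the
    parity-respecting finite-size crossing equation for theta-temperature
    estimates, and extrapolates the odd- and even-parity series to infinite
    chain length with Neville and Bulirsch-Stoer tableaus, including the
    parity-paired omega scan and the derivative-ratio estimator of the
    crossover exponent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    readr,
    ggplot2,
    generics,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
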