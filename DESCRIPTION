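Package: nqdist
Title: Non-Quadratic Statistical Distances for Model Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical distances that are not quadratic forms, used as loss
    functions for assessing model misspecification: total variation, Hellinger
    and Matusita/affinity relatives, the Kullback-Leibler divergence with its
    likelihood, J-divergence and chi-squared companions, and the mixture index
    of fit (pi-star), for both finite discrete distributions and univariate
    continuous models. Continuous comparisons smooth the sample with a normal
    kernel before computing distances, which avoids the degenerate total
    variation of one between discrete and continuous measures. Includes a
    contamination-model Monte Carlo study runner that evaluates the distances
    as measures of model misspecification, brute-force oracles for the key
    closed forms, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
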