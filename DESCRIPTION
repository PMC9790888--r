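Package: cryoevolve
Title: Closed-Loop Machine-Learning Optimization of Sperm Cryopreservation
    Extender Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Surrogate-assisted differential evolution for designing bull
    sperm cryopreservation extender media over an eleven-component
    formulation space. Implements the DE/rand/1/bin optimizer with a
    late-campaign reference-value jitter, feed-forward neural-network and
    Gaussian-process-regression surrogates of post-thaw motility with
    ten-fold cross-validated model selection, Wellek's Mann-Whitney test
    for equivalence alongside rank-based omnibus, post-hoc and
    variance-homogeneity tests, and a configurable synthetic "virtual lab"
    motility simulator with among- and within-bull variability so the full
    closed loop can be exercised end to end without live animals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lhs,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
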