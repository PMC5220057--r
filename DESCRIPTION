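Package: seedbankIBM
Title: Individual-Based Simulation of Microbial Seed Banks and Resource Encounter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic, spatially explicit individual-based models of
    microbial communities in which seed banks (dormant subpopulations)
    emerge from microscale encounters between cells and resource
    particles. Simulates factorial combinations of trophic, resource,
    dispersal, and mixing complexity (72 regimes), with randomized
    parameterization, encounter-limited consumption, resource particle
    fragmentation, energetic costs of dispersal and growth, and
    stochastic transitions into and out of dormancy. Includes an
    ensemble runner with burn-in detection by mean reversion, a metrics
    suite (abundance, productivity, percent dormancy, encounter rates,
    species abundance distributions), and a Fisher log-series
    goodness-of-fit statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
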