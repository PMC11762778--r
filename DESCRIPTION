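Package: telosim
Title: Stochastic Simulation of Telomere Shortening and Replicative
    Senescence in Budding Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An agent-based stochastic model of telomere shortening and
    replicative senescence in telomerase-negative Saccharomyces
    cerevisiae.  Cells carry the full 2 x 16 matrix of telomere lengths;
    at each division one telomere per chromosome is shortened by the
    replication overhang, coupled between the two daughters.  Cell fate
    (non-terminal arrest, terminal senescence, accidental death) follows
    probability laws of the shortest telomere in the cell.  The package
    simulates single-cell lineages as observed in microfluidics devices,
    and competing cell populations under daily saturation-dilution
    culture, including in-silico perturbations of the initial telomere
    length distribution and of telomere-independent mortality, plus
    CMA-ES calibration of the arrest laws with parameter-recovery
    validation on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
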