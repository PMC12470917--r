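Package: latticeplate
Title: Risk-Aware Design of Porous Titanium Reconstruction Plates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale design loop for patient-specific porous Ti-6Al-4V
    reconstruction plates bridging segmental bone defects. Calibrates a
    Gibson-Ashby porosity law from lattice-coupon moduli, builds a parametric
    synthetic bone-plate-lattice construct on a structured hexahedral mesh,
    solves linear-elastic equilibrium with von Mises recovery, sweeps a
    full-factorial or Latin-hypercube design of experiments, trains a
    multi-output neural surrogate of the three mechanical targets, propagates
    bone-modulus, bite-force and build-porosity scatter by Monte Carlo to
    exceedance probabilities, and runs a risk-constrained multi-objective
    genetic search that returns a Pareto set of lightweight, mechanically
    safe plate designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    pracma
Config/testthat/edition: 3
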