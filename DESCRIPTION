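Package: nscdyn
Title: Neural Stem Cell Population Dynamics Under Interferon Signalling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling adult neural stem cell (NSC) population
    dynamics in the ventricular-subventricular zone. Implements a
    two-compartment quiescent/active NSC ordinary-differential-equation model
    with time- or population-dependent activation and self-renewal laws,
    multi-start box-constrained weighted-least-squares parameter estimation
    with AICc model selection across genotypes (wild type and
    interferon-receptor knockout), and intervention simulations that switch
    parameter regimes at arbitrary ages to score stem-cell retention and
    life-long progenitor production. Also provides the auxiliary statistics
    used alongside the model: a change-time (biphasic) step-regression test
    for signalling time courses, a 5'TOP motif classifier for mRNA 5'UTRs,
    and per-cell gene-signature scoring for count matrices, plus synthetic
    data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    Biostrings,
    withr,
    optparse
Config/testthat/edition: 3
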