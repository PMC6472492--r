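Package: debevo
Title: Size-Structured Consumer-Resource Dynamics and the Evolution of
    Metabolic Scaling Exponents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a size-structured consumer-resource model based on a
    net-production dynamic energy budget, in which maximum ingestion and
    maintenance metabolism scale with body mass as power functions with
    exponents Q and P. Provides individual-level life-history integration at
    fixed resource density, solution of the ecological equilibrium from the
    lifetime-reproductive-success condition R0 = 1, cohort-based (Escalator
    Boxcar Train) simulation of non-equilibrium population dynamics, and
    adaptive-dynamics machinery (selection gradients, singular strategies,
    evolutionary isoclines, joint continuously stable strategies and their
    parameter sweeps) for the two scaling exponents. Also includes reduced
    major axis regression with confidence intervals and a synthetic generator
    for interspecific metabolic-exponent data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
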