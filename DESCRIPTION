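Package: flushrisk
Title: Flush-Distance Risk Models and Deceptive Nest-Defence Analysis for
    Ground-Nesting Shorebirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying deceptive nest defence in uniparental
    ground-nesting shorebirds. Implements an analytic flush-initiation-distance
    risk model (detection probability times a squared-law flush probability,
    with the location of maximum risk), a Monte Carlo predator-encounter
    simulator that serves as a brute-force check on the analytic model and
    generates nest-fate outcomes for populations of flush strategies, a
    synthetic nest-record generator emulating field datasets, and the
    statistical pipeline used on such records: Hartigan's dip test of
    unimodality, proportional-odds ordinal regression of defence behaviour,
    quadratic binomial logistic regression of nest fate, two-sample t tests and
    descriptive summaries. Includes delimited-table readers/writers with
    validation and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
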