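Package: kinmech
Title: Automated Discovery of Parsimonious Mass-Action Reaction Mechanisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the simplest mass-action reaction mechanism consistent
    with concentration-time data. Candidate mechanisms are enumerated as
    integer stoichiometric matrices by a pruned, parallelisable backtracking
    search under physical feasibility rules, translated into mass-action
    ordinary differential equation models, fitted to multi-experiment data by
    multistart bounded quasi-Newton minimisation of the sum of squared
    errors, and ranked by the Akaike information criterion; mechanism
    complexity (elementary steps and hidden intermediates) grows iteratively
    until the criterion stops improving. Also provides a model-discrimination
    experiment designer (Hunter-Reiner criterion) and seeded in-silico
    case-study data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
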