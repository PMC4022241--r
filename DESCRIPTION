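Package: instcho
Title: Non-Stationary 13C Metabolic Flux Analysis of CHO Batch Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmented metabolic flux analysis for mammalian batch
    cultures from the time course of extracellular mass isotopomer
    distributions. Provides a metabolic network model with carbon atom
    transitions, free-flux extraction from the stoichiometric system,
    metabolite balancing for growth and cell-specific rates, GC-MS
    natural-abundance correction, forward simulation of isotopomer
    dynamics via isotopomer mapping matrices with time-varying transport
    reversibilities, and global parameter estimation with chi-squared
    model discrimination, profile-likelihood confidence intervals and
    sensitivity analysis. Includes a synthetic-data generator emulating
    a CHO-K1 batch labeling experiment on [U-13C6] glucose.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
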