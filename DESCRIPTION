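Package: demefrag
Title: Fixation of Mutants with Proportionally Scaled Birth and Death Rates
    in Fragmented Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulators and coarse-grained analytic theory for the
    fate of mutants whose birth and death rates are proportionally scaled by a
    turnover factor and whose lifetime reproductive output is changed by a
    selection coefficient.  Provides an exact Gillespie simulation of
    deme-structured logistic birth-death dynamics with density-controlled
    migration, a spatially explicit agent-based model on a toroidal lattice,
    exact finite-Markov-chain solvers for within-deme invasion probabilities
    and quasi-stationary deme-size distributions, and closed-form results for
    well-mixed and death-birth Moran populations.  Together these quantify how
    population fragmentation turns quasi-neutral fast-turnover variants into
    genuinely disadvantageous ones (and slow-turnover variants into
    advantageous ones), including full reversal of selection for mutants with
    altered lifetime reproductive output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
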