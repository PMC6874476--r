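Package: chemostates
Title: Multistability and Regime Shifts in Chemostat Communities Competing
    for Essential Nutrients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consumer-resource model of microbial communities growing in a
    chemostat on two classes of essential nutrients (several carbon and
    several nitrogen metabolites), with growth set by Liebig's law of the
    minimum. Enumerates every steady state allowed by the competitive
    exclusion rules, classifies states by invadability, structural
    stability (Monte-Carlo feasibility over nutrient supply rates) and
    dynamic stability (perturbation of the stiff ODE system, or inference
    from multiplicity patterns), builds the network of regime shifts and
    smooth transitions between alternative stable states, and computes
    downstream multistability, diversity and stoichiometry statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
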