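Package: switchmig
Title: Probabilistic Cellular Automaton of Amoeboid-Mesenchymal Migration Plasticity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tumor cell invasion on a two-dimensional lattice with a
    probabilistic cellular automaton in which cells switch between a fast,
    non-degrading amoeboid migration mode and a slow, matrix-degrading
    mesenchymal mode in response to local extracellular-matrix (ECM)
    resistance. Cell movement is a chemotactically biased exclusion process;
    mesenchymal cells locally degrade the ECM. The package provides
    generators for homogeneous and structured-plus-noise heterogeneous ECM
    resistance fields, migration-distance observables, and a reproducible
    experiment harness covering switch-ratio scans, critical-resistance
    scans, heterogeneity/migration-ratio phase diagrams, chemotactic
    sensitivity analyses, and population-cooperativity comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
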