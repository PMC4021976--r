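Package: brainflux
Title: Constraint-Based Modeling of Neuron-Astrocyte Energy Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a four-compartment stoichiometric network of
    compartmentalized brain energy metabolism (neuron, astrocyte,
    extracellular space, blood capillary), samples its Von Neumann
    feasible-flux polytope (S v >= 0 for internal species, mass balance
    for nutrient intakes, fixed capillary glucose uptake) with a
    prior-seeded relaxation algorithm, and computes the derived
    observables: the oxygen-to-glucose index (OGI), the
    glutamate-glutamine cycle rate V_cyc, neuronal oxidative glucose
    metabolism, glucose partitioning between cell types, and the
    cell-to-cell lactate shuttle, together with conditional averages and
    flux correlation structure. Small synthetic benchmark networks with
    enumerable solution polytopes provide independent oracles for the
    sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
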