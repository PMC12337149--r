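Package: umdkin
Title: Ligand (Un)binding Kinetics, Pathways and Gating from Unbiased MD
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for gas-ligand binding and unbinding in
    unbiased molecular-dynamics simulations of buried-site enzymes such as
    [NiFe] hydrogenases. Labels each ligand copy per frame as bound,
    intermediate or unbound from geometric criteria; extracts binding and
    unbinding events with first-passage and residence times; estimates
    association (k_on) and dissociation (k_off) rate constants with
    bootstrap uncertainties; assigns events to protein tunnels from
    sphere-based tunnel geometries and tests binding/unbinding pathway
    symmetry with chi-square tests; computes bottleneck residue-pair
    minimum distances with a two-state (open/closed) classification; and
    builds discrete Markov state models with stationary-reweighted
    free-energy landscapes. Includes a Brownian-dynamics toy-system
    generator with recorded ground truth so the full pipeline is testable
    without large trajectory downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
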