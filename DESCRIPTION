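Package: paircomm
Title: Pair Approximation and Lattice Simulation of Two-Type Spatial
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives community-level steady-state properties of spatially
    structured two-type microbial communities (composition, local spatial
    structure, productivity, collapse) from the local interaction rules
    between cells, and derives those local rules (interaction range,
    neighborhood size, maximum growth rate) from the biophysical parameters
    of the underlying molecular exchange (diffusion, uptake and leakage
    rates, cell geometry and density). The community layer is a pair
    approximation on directed regular graphs that permits different
    neighborhood sizes for the two cell types; predictions are validated
    with a stochastic cellular automaton on a periodic lattice with
    per-type extended Moore interaction ranges. Includes spatial
    observables on lattice snapshots, a clustered-versus-randomized
    productivity experiment, and a configuration-driven pipeline from
    molecular parameters to community predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
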