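Package: duallattice
Title: Dual-Lattice Simulation of the Evolution of Mutualism from Parasitism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how mutualistic symbiosis can evolve from
    parasitism when costs and benefits are routed separately to the two fitness
    components, fecundity and survival. Implements a two-species dual-lattice
    model in which each individual interacts with the occupant of the same site
    on the partner species' toroidal grid: mean-field frequency dynamics under
    unlimited dispersal (including the analytic selection differential showing
    mutualists always decline in a well-mixed population), a seeded Monte-Carlo
    lattice engine under limited dispersal, and invasion-experiment protocols
    (mutant introduction, reciprocal invasion, population-size ratios, binary
    strategy screens and cost/benefit parameter sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
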