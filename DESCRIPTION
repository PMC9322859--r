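Package: lusim
Title: Multi-Scenario Land-Use Simulation and Habitat-Quality Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled Markov chain / cellular-automaton simulation of categorical
    land-use change under named policy scenarios, with an InVEST-style
    threat-decay habitat-quality model to score the simulated landscapes.
    Includes a synthetic-landscape generator (autocorrelated six-class maps,
    class-correlated driver surfaces, road networks, and epoch transitions
    governed by a known matrix) so the full pipeline is testable without
    proprietary rasters, an artificial-neural-network land suitability stage,
    adaptive-inertia roulette allocation, raster cross-tabulation change
    accounting, and ESRI ASCII grid input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
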