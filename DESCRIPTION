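Package: dbfba
Title: Differential-Evolution Bees Search over Flux Balance Analysis for
    Strain Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based design of microbial production strains by
    reaction knockout. Couples flux balance analysis (FBA) with a bees
    algorithm whose neighbourhood search is performed by differential
    evolution (DE), scoring candidate knockout sets by biomass-product
    coupled yield (BPCY). Includes model I/O for SBML (Level 3 + FBC) and
    BiGG-style JSON, model reduction (blocked-reaction removal, essential-
    reaction protection), a bilevel strong-duality OptKnock formulation
    solved by branch and bound for validating heuristic solutions, a
    continuous benchmark-function harness for comparing the DE-hybridised
    and classic bees searches, and synthetic toy-network generators with
    exhaustive oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xml2,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
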