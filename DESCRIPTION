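Package: efmtools
Title: Selection, Analysis and Network Export of Elementary Flux Modes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for working with elementary flux modes (EFMs) computed
    from genome-scale metabolic models. Reads SBML models (Level 2 and
    Level 3 with the fbc and groups packages), parses EFM and relative-flux
    files, selects EFMs by reaction presence, product yield, or
    over-representation of differentially expressed genes mapped through
    gene-protein-reaction rules, extracts single-EFM submodels back to
    SBML, profiles subsystem occurrence and backbone reactions across EFM
    collections, and exports annotated bipartite metabolite-reaction(-gene)
    networks to GraphML, SIF, and JSON for visualization tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
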