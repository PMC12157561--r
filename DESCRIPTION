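Package: polarvk
Title: Circular van Krevelen Maps for Metabolic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Lays out and draws metabolic pathway maps on a coordinate system
    computed purely from chemical formulas. Every compound receives a fixed
    position from its elemental ratios: the H:C ratio maps to the angular
    coordinate and a mass-weighted heteroatom ratio (NOPS:C) to the radial
    distance, so the same compound always lands at the same point regardless
    of which pathway it is drawn in. Includes a Hill-notation formula parser
    with isotope support, readers and writers for plain tab-separated pathway
    tables, quantitative overlay annotation, deterministic node-overlap
    resolution, SVG and PNG rendering of single maps and multi-pathway panels,
    synthetic pathway generators for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    readr,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    png,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
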