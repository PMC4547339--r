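Package: pathlanes
Title: Merged Multi-Pathway Graphs with Set-Membership Lane Overlays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a node-deduplicated directed graph from multiple
    biological pathways (read from a BioPAX Level-3 subset or a JSON
    pathway dialect), derives binary reaction relationships from
    multi-participant biochemical reactions, computes a layered
    top-to-bottom layout with feedback-arc handling and side-by-side
    colored edge lanes encoding pathway membership, answers
    reachability and filtering queries over view states, inspects
    nested protein-complex hierarchies through packed overviews and
    pruned trees, and renders any view state to deterministic SVG.
    Includes a seeded synthetic pathway-set generator and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
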