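Package: interologr
Title: Interolog-Based Prediction and Analysis of Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Transfers experimentally observed protein-protein
    interactions from reference species onto a target species through
    ortholog clusters (the interolog method), scores each predicted
    interaction with a confidence value CV = N x S x E, and analyses the
    resulting network: degree distribution and hub classes,
    characteristic path length, conserved subnetworks, bait-and-prey
    neighbourhoods, GO term enrichment and depletion, co-expression
    support from M-value profiles, and overlap validation against an
    independent experimental interaction set. Ships a synthetic fixture
    generator that plants ground truth for every pipeline stage and a
    command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
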