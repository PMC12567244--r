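Package: cdftrank
Title: Conceptual-DFT Reactivity Descriptors, ESP Surface-Area
    Quantification and Composite Bioactivity Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes conceptual-DFT global reactivity descriptors
    (electronegativity, hardness, softness, electrophilicity, charge-transfer
    capacity) from frontier-orbital energies, quantifies positive, negative
    and neutral surface areas of rendered molecular electrostatic potential
    (MEP) maps by HSV color thresholding, combines both into a weighted
    Composite Bioactivity Score with cohort-wise min-max normalization and
    deterministic ranking, and derives selectivity indices from IC50 tables.
    Ships a synthetic-data generator that produces descriptor cohorts,
    MEP-style images with exact per-class pixel ledgers, ESP extrema and
    IC50 tables with known ground truth, so every stage of the pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jpeg,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
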