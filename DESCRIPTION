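Package: netpharmbiome
Title: Network Pharmacology and Gut-Microbiome Statistics for Herbal
    Formula Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to reproduce the computational core of herbal-formula
    network-pharmacology studies of experimental colitis: ADME filtering of
    herb compounds, herb-ingredient-target network assembly, multi-source
    disease-gene collation, confidence-filtered protein-protein interaction
    graphs with iterative six-centrality hub extraction, hypergeometric
    over-representation analysis with Benjamini-Hochberg adjustment,
    downstream 16S feature-table statistics (low-abundance filtration,
    composition profiles, alpha and beta diversity, PCoA, non-metric
    multidimensional scaling, UPGMA clustering, and a LEfSe-style biomarker
    screen), a disease-activity-index scoring rubric for DSS colitis, and
    seeded synthetic-data generators with planted ground truth for every
    pipeline input.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    ape,
    optparse
Config/testthat/edition: 3
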