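Package: scatlas
Title: Single-Cell Tumor Atlas Statistics: CNV Malignancy Calling,
    Marker Selection, Tissue Preference and Receptor-Ligand Networks
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Reusable implementations of the bespoke statistics used in
    droplet single-cell RNA-seq tumor atlas studies: expression-inferred
    copy-number perturbation and malignant-cell classification, threshold
    based differential marker and signature statistics with survival
    stratification, chi-square tissue-preference measures (Pearson
    residuals and observed/expected ratios), a permutation-based
    receptor-ligand cell-cell interaction network with stepwise filters,
    and a gene-gene functional association network from Jaccard similarity
    of Gene Ontology term sets. A seeded negative-binomial cohort
    simulator with planted copy-number segments, marker blocks, tissue
    preferences and receptor-ligand signals makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    survival,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
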