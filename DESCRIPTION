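Package: ppirpredict
Title: Predicting Protein-Protein Interface Localization of
    Post-Translational Modification Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps post-translationally modified residues to locations
    inside or outside protein-protein interacting regions (PPIRs) and
    learns sequence-based predictors for sites without structural
    coverage.  Builds per-residue interface maps from atomic coordinates
    by Van der Waals contact detection between polypeptide chains,
    labels 15-residue modification-site windows by exact sequence
    matching against the map, encodes windows with amino-acid property
    scales (AAindex) using a centre-subtraction scheme, corrects class
    imbalance by Gibbs-sampling motif clustering with proportional
    under-sampling, ranks and greedily selects property scales and
    individual features by a combined performance score (accuracy +
    AUC + Matthews correlation), and evaluates support-vector-machine
    and k-nearest-neighbour classifiers under repeated stratified
    cross-validation.  Includes generators for synthetic complexes,
    windows and motif families so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    kernlab,
    class,
    jsonlite,
    withr,
    Biostrings,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
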