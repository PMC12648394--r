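Package: phyloModules
Title: Phylogenomic Association of Sequence Conservation Modules with Protein Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects local sequence-conservation modules (ungapped blocks of
    significantly similar segments shared by at least two proteins) in a
    multi-functional protein family, infers each module's presence at every
    ancestral node of the family's rooted binary gene tree via module-tree
    construction and duplication-transfer-loss reconciliation (with a Dollo
    parsimony baseline and replicate support frequencies), reconstructs
    ancestral presence of binary functional annotations by maximum likelihood
    under a two-state Markov model, and proposes module signatures of
    functions from their co-emergence at ancestral gene nodes. Includes a
    synthetic data generator with ground-truth manifests and iTOL annotation
    writers for interactive exploration of the annotated gene tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Phylogenetics, Alignment, Annotation, FunctionalPrediction
RoxygenNote: 7.3.3
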