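Package: kipred
Title: Kinase-Inhibitor Interaction Prediction from Paired Sequence and
    Structure Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for predicting binary binding between protein kinases
    and small-molecule inhibitors from concatenated pair features. Generates
    kinase descriptors (PROSITE-style pattern hits, frequent amino-acid
    sequence patterns with wildcards, phylogenetic annotations, global and
    conserved-frame alignment score vectors, position-specific active-site
    residues and their physico-chemical classes) and inhibitor descriptors
    (maximal frequent free-tree substructures, physico-chemical and geometric
    descriptors, topological 3-point pharmacophores, binding-profile
    k-nearest-neighbour similarities), assembles kinase-inhibitor pair
    instances, wraps decision-tree and support-vector classifiers, and
    evaluates them under four leave-one-out cross-validation variants (hard,
    soft, mixed, mixed-mixed) against majority-class and probability-product
    baselines. Includes a synthetic dataset generator with a plantable
    feature-to-binding rule for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
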