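Package: seagba
Title: Ligand-Set Similarity Networks and Neighbor-Voting Gene Function
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds protein networks from ligand-set chemical similarity
    (summed fingerprint Tanimoto scores calibrated against a random
    background and expressed as extreme-value E-values, the Similarity
    Ensemble Approach), alongside sequence-similarity, co-expression and
    path-extended physical-interaction networks, all rank-standardized
    into a common [0,1] edge-weight scale.  Evaluates each network, and
    their aggregates, for gene function prediction by neighbor-voting
    guilt-by-association with cross-validated AUROC and average
    precision, including node-degree and label-permutation null
    baselines, cross-network concordance statistics, top-fraction
    sparsification, and greedy annotation-overlap pruning.  A synthetic
    data generator plants chemotype families, co-expression modules and
    interaction blocks with aligned annotations so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
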