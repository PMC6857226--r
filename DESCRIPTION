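Package: dcbench
Title: Simulation and Benchmarking of Differential Co-Expression Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates gene expression data from signed regulatory networks
    using a normalised-Hill steady-state model with gene knockdown
    conditions, derives nested "truth" differential networks (direct,
    influence, association) by deterministic perturbation-sensitivity
    analysis, implements network-based differential co-expression statistics
    (Fisher z-score, soft-thresholded correlation difference, interaction
    linear models, conditional mutual information, and co-expression
    difference baselines), and evaluates inferred networks with pooled
    precision, recall and F1 across truth levels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
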