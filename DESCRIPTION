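Package: posefilter
Title: Interaction-Pattern Filtering and Rescoring of Docked Protein-Ligand Poses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts atomic interaction pairs (ligand heavy atom versus
    three-heavy-atom protein fragment within 5 Angstrom of the fragment
    anchor) from protein-ligand complexes in PDB format, learns significant
    interaction patterns per (SYBYL atom type, fragment type) group with a
    variational Bayesian-Gaussian mixture model, and rescores docked poses
    with two statistics (significant-pair count and significant-pair ratio),
    threshold rules, and a two-feature probability classifier. Includes a
    validation harness (ligand RMSD labelling, ROC with Youden-index cutoff
    selection, confusion metrics, train/test splitting, five-classifier
    comparison) and deterministic synthetic-fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    class,
    rpart,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
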