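Package: acfnb
Title: Atom-Center Fragments and Bayesian Classification of Compound Activity
Version: 0.1.0
Authors@R:
    person("acfnb", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Ligand-based binary activity classification for compound
    libraries. Parses SMILES/SDF input into heavy-atom molecular graphs,
    computes a 13-descriptor physicochemical panel, sparse circular
    (ECFP-style) fingerprints and atom-center fragments (ACF), and trains
    Laplacian-corrected naive Bayesian and depth-bounded recursive
    partitioning classifiers. Includes Bayesian fragment ranking for
    privileged-substructure analysis, a full confusion-matrix evaluation
    suite (sensitivity, specificity, per-class precision, Matthews
    correlation, ROC/AUC), cross-validation drivers, a synthetic-library
    generator with planted class-defining substructures, and a command-line
    interface for the featurize/train/predict workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
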