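Package: sdar3d
Title: Spectral Data-Activity Relationship Modeling of Torsade-de-Pointes Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds three-dimensional spectral data-activity relationship
    (3D-SDAR) classification models for drug-induced Torsade-de-Pointes
    (TdP) cardiotoxicity risk. Atom-pair fingerprints are constructed from
    per-atom 13C and 15N NMR chemical shifts combined with interatomic
    distances and tessellated into a binned (shift, shift, distance) space.
    Compounds are classified by an ensemble of multilayer perceptrons
    trained by full-batch gradient descent with weight decay and early
    stopping on random 25 percent holdouts, aggregated by the median of
    member predictions. Mean-substitution sensitivity analysis ranks bins
    by importance, and significant bins are back-projected onto active
    compounds as 3D toxicophore features, with distances reported relative
    to aromatic-ring centroids. Includes readers for MOL/SDF structures and
    shift tables, a pluggable chemical-shift provider interface, a
    synthetic planted-rule data generator for end-to-end validation, and a
    command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    methods,
    pROC,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
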