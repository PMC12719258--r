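Package: dbrbc
Title: Dual-Layer Belief Rule Base Classification with Contribution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical (coarse-to-fine) belief rule base classification for
    multilevel risk stratification on tabular physiological and behavioral
    data. Implements evidential-reasoning forward inference over conjunctive
    belief rules, cascaded differential-evolution / particle-swarm parameter
    learning of rule weights, attribute weights and belief degrees, reverse
    contribution analysis (attribute reconstruction from output belief
    distributions) with a class-by-attribute contribution belief matrix,
    two-stage feature selection (gradient-boosting gain threshold followed by
    sequential forward selection), stratified data splitting, and a synthetic
    cohort generator for BMI-derived obesity classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
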