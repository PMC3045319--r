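Package: orgfocus
Title: Focus-Organism Classification for Biomedical Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for classifying biomedical abstracts and full-text
    articles by their focus model organism (fly, mouse, yeast by default).
    Provides a line-delimited corpus format with section segmentation and
    rule-based tokenization, lexicon-driven gene and organism mention
    tagging, a title-based triage rule, gene-distribution content selection,
    eight document feature extractors including a distance-weighted
    term-species score, from-scratch multinomial Naive Bayes with bagging
    and AdaBoost.M1 ensembles and a section-sequence aggregation classifier,
    stratified k-fold and repeated cross-validation with the corrected
    resampled t-test, a feature-ablation harness, and a seeded synthetic
    corpus generator for end-to-end evaluation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
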