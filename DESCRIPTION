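Package: hypomimia
Title: Facial Expression and Action Unit Domains for Parkinson Hypomimia Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable implementation of a three-level framework for detecting
    hypomimia (reduced facial expressivity in Parkinson's disease) from elicited
    facial expressions: (i) expression stage segmentation (neutral, onset, apex,
    offset, neutral) on per-clip activation curves and multi-frame sequence
    assembly; (ii) facial action unit (AU) detection models (a ResNet50 face
    backbone adapted by layer freezing, plus compact VGG-8 and ResNet-7 networks
    trained from scratch) evaluated with AUC and equal error rate; and (iii)
    expression-constrained triplet-loss metric learning producing Parkinson-domain
    embeddings. Classification between patients and controls uses support vector
    machines under nested subject-independent cross-validation with grid search,
    and models are compared by repeated cross-validation with Kruskal-Wallis and
    Bonferroni-corrected Mann-Whitney tests. Because clinical video corpora of this
    kind are private, the package ships a procedural synthetic-face cohort
    generator with controllable hypomimia (reduced amplitude, slowed onset) so the
    whole pipeline is exercisable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    withr,
    kernlab,
    pROC,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
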