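Package: sketchlatent
Title: Latent Structure Metrics for Human Figure Drawings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives machine-based and human-judgment-based latent embeddings of
    children's human figure drawings together with a crowd-sourced quality-rank
    score, compares these metrics with the classic 12-item Draw-A-Child checklist,
    and quantifies how much variance each metric explains in participant
    characteristics (age, gender, motor and behavioral scores) through a stepwise
    nested-model harness. Includes classical multidimensional scaling of cosine
    similarities over image features, crowd-kernel ordinal embedding from triplet
    judgments with holdout evaluation and dimension selection, pairwise
    forced-choice quality ranking, nearest-neighbor concordance between embedding
    spaces, and repeated-holdout AUC for binary outcomes. A synthetic-study
    generator produces drawings, participants, simulated human judgments, and
    outcome scores so the entire pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
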