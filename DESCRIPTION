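Package: drugvnn
Title: Ontology-Guided Visible Neural Networks for Drug Survival Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts cancer patient survival from a transcriptome profile
    and a prescribed drug's chemical structure with a visible neural network
    whose expression encoder is wired after the Gene Ontology hierarchy.
    Provides OBO parsing and annotation-driven pruning of the ontology,
    Morgan-style circular fingerprints for drugs, censoring-aware two-stage
    training (binary vital-status pretraining followed by months-to-death
    regression with encoder weight transfer), attention-based discovery of
    discriminating ontology terms, exhaustive in-silico optimal-drug
    selection, a rare-drug support filter against the memorization effect,
    and a synthetic cohort generator with planted ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
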