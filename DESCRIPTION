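Package: scmcard
Title: Scoring Card Method for Protein Functional-Class Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the scoring card method (SCM) for predicting whether
    a protein belongs to a functional class from its primary sequence alone.
    A scoring card assigns each of the 400 ordered dipeptides a propensity
    score on a [0, 1000] scale, estimated from the dipeptide-composition
    difference between positive and negative training sequences and refined
    by an elitist genetic algorithm whose fitness combines cross-validated
    ROC AUC with the correlation to the initial card. Sequences are scored
    by the composition-weighted sum of dipeptide scores and classified
    against a threshold chosen to maximise training accuracy. Also provides
    the SCM-PCP analysis that correlates the derived 20 amino-acid
    propensity scores with AAindex physicochemical property indices to
    characterise the class, a synthetic sequence generator with planted
    dipeptide enrichment for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
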