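Package: amylopair
Title: Amyloid Hot-Spot Prediction from Position-Specific Residue-Pair
    Co-Occurrence Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies short peptides and scans full-length proteins for
    amyloidogenic "hot spot" segments. The classifier learns a
    position-specific amino-acid pair co-occurrence pattern from positive
    peptides, selecting one most pattern-bearing window per positive
    sequence by an iterative distance-maximization procedure against the
    averaged pattern of negative sliding windows, and scores new sequences
    by a distance-ratio statistic over sliding windows. Includes ROC/AUC
    evaluation with repeated stratified cross-validation, a bundled prion
    sup35 fragment test set, a synthetic planted-motif data generator, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    Biostrings,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
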