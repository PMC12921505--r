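Package: indellm
Title: Length-Aware Zero-Shot Pathogenicity Scoring for In-Frame Protein Indels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Zero-shot pathogenicity scoring of in-frame protein insertions and
    deletions from protein-language-model per-position probabilities. Implements
    pseudo-log-likelihood (PLL) scoring of wild-type/mutant sequence pairs, an
    overlap-restricted sum-of-probabilities score that removes the length bias of
    PLL differences, masked and absolute-value variants, and per-residue
    probability-difference tracks exportable onto protein structures via the PDB
    B-factor column. Also provides a lightweight Siamese transfer-learning
    classifier over sliced sequence embeddings, identity-cluster-aware stratified
    dataset splitting, classification metrics (MCC, F1, ROC/AUC, Youden-optimal
    thresholds), a truncation rule for sequences exceeding model capacity, and a
    deterministic synthetic probability/embedding backend for fully offline runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
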