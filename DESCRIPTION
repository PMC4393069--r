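Package: sumohunt
Title: SUMOylation Site Prediction from Physicochemical Peptide Encodings
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts SUMOylation of protein lysine residues from the local
    sequence context. Lysine-centered peptide windows are encoded with sixteen
    amino-acid physicochemical property scales (AAIndex) per position and
    classified by a small bagged ensemble of randomized Gini decision trees
    voting by majority. Includes dataset curation from FASTA plus site
    annotations (window extraction, exact-duplicate removal, class balancing),
    WEKA-compatible ARFF/CSV export, a full evaluation battery (percentage
    split, k-fold cross-validation, leave-one-out, self-consistency;
    sensitivity, specificity, accuracy, Matthews correlation, ROC/AUC),
    positional residue-frequency analysis around the target lysine, psi-K-x-E
    consensus-motif matching, and deterministic synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    foreign,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
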