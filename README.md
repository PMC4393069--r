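# sumohunt

Prediction of SUMOylation sites on protein lysine residues from the local
sequence context, for proteomics researchers who want to rank candidate
lysines before committing to wet-lab validation.

SUMOylation — covalent attachment of the SUMO protein to specific lysines —
regulates localization, transcription, transport and many other processes,
but only some lysines in a protein are modified. The classical consensus
motif ΨKXE (hydrophobic Ψ, target K, any residue, glutamate at +2) misses
roughly a quarter of validated sites and over-calls many unmodified ones.
`sumohunt` instead represents each candidate site as a lysine-centered
peptide window of length 2f+1 (windows of 7, 11 or 21 residues) and encodes
every position with sixteen AAIndex physicochemical property scales
(hydrophobicity, polarity, bulkiness, hydropathy, accessibility, buriability
and related measures), giving a 16·(2f+1)-dimensional feature vector — 112,
176 or 336 features. A random forest classifies the vectors: each of B
(default 10) trees grows on a bootstrap sample, considers mtry =
⌊log₂ M⌋ + 1 random features per node, splits by Gini impurity decrease,
and the trees vote by majority.

Evaluation follows the standard battery for site predictors: percentage
split, k-fold cross-validation, leave-one-out (jackknife) and
self-consistency, each reporting

    SN = TP/(TP+FN)   SP = TN/(TN+FP)   AC = (TP+TN)/N
    MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))

plus ROC/AUC by the mid-rank Mann–Whitney statistic.

The package also ships the curation pipeline (FASTA + site annotations →
labeled, deduplicated, class-balanced window datasets; WEKA-compatible
ARFF/CSV export), positional residue-frequency analysis around the target
lysine, ΨKXE consensus matching, and deterministic synthetic-data
generators so every stage is testable without external downloads.

## Worked example

Build the synthetic benchmark (293 positive windows drawn from the packaged
positional-composition model of curated modified sites, 293 uniform-background
negatives), train the default forest, and evaluate a 93% percentage split at
window size 7:

```r
library(sumohunt)

bench <- make_benchmark(n_pos = 293, n_neg = 293, seed = 42, flank = 3)
bench$encoded
#> encoded_dataset: 586 instances x 112 features (flank 3); 293 positive / 293 negative

model <- train_forest(bench$encoded, n_trees = 10, seed = 42)
model
#> sumo_forest: 10 trees, mtry 7, 112 features; trained on 293 positive / 293 negative instances (seed 42)

plan <- percentage_split(bench$encoded, train_pct = 93, seed = 42)
evaluate_split(bench$encoded, plan, seed = 42)
#> [split 93%] AC 88.10%  SN 82.61%  SP 94.74%  MCC 0.77  AUC 0.95  (TP 19 FP 1 TN 18 FN 4)
```

The 586-instance set splits into 544 training and 42 held-out windows; of
the 23 held-out positives 19 are recovered (SN 82.61%), of the 19 held-out
negatives 18 are rejected (SP 94.74%), for 88.10% accuracy, MCC 0.77 and
AUC 0.95. The positional signal the model learns is visible directly in the
positive windows:

```r
pos  <- subset(bench$windows, label == "positive")
posw <- window_dataset(pos$peptide, pos$label)
consensus_fraction(posw)
#> [1] 0.655                       # fraction of positives matching ΨKXE
positional_frequency(posw)["E", "+2"]
#> [1] 227                         # glutamate at +2 in 227 of 293 windows
```

Real data enters through the same interfaces: `read_fasta_sequences()` +
`read_sites()` + `build_windows()` (then `deduplicate()`, `balance()`),
or the command-line wrapper `inst/scripts/sumohunt.R` with the verbs
`build-dataset`, `train`, `predict`, `evaluate`, `freq`, `simulate`.

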