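---
title: "Predicting SUMOylation sites from physicochemical peptide encodings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting SUMOylation sites from physicochemical peptide encodings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumohunt)
```

## The problem and the model

SUMOylation attaches the small SUMO protein to particular lysine residues of
a target protein. Which lysines are modified is only partly explained by the
classical consensus motif ΨKXE (hydrophobic residue, target lysine, any
residue, glutamate): roughly a quarter of validated sites lie outside it,
and many consensus matches are never modified. The working hypothesis behind
this package is that the local physicochemical environment of the lysine —
hydrophobicity, polarity, bulkiness, accessibility, side-chain volume and
similar properties that control how the residue is presented to the
conjugation machinery — carries signal beyond the raw sequence pattern.

A candidate site is represented as a lysine-centered peptide window of
length $2f+1$ (flank $f \in \{3, 5, 10\}$, i.e. windows of 7, 11 or 21
residues). Each position is encoded with sixteen amino-acid property scales
drawn from the public AAIndex collection, giving a feature vector of
dimension $16(2f+1)$: 112, 176 or 336. The ordering is position-major (the
sixteen properties of offset $-f$, then of $-f{+}1$, and so on); feature
names such as `pos-3:PRAM900101` record the layout so any consumer can
verify it. Raw coefficients are used — the scales are not standardized by
default, since tree-based classifiers are invariant to monotone per-feature
rescaling; a `standardize` switch exists for use with other downstream
models.

The classifier is a random forest in the original bagging-plus-random-
subspace form: each of $B$ trees is grown on a bootstrap sample ($n$ draws
with replacement) of the training windows; at every node a uniform random
subset of `mtry` features is considered and the best axis-aligned split by
Gini impurity decrease is taken, with thresholds at midpoints of adjacent
distinct values; trees grow until leaves are pure (minimum leaf size 1).
Trees vote and the majority class wins. The default is deliberately small —
$B = 10$ trees with `mtry` $= \lfloor \log_2 M \rfloor + 1$ for $M$
features — matching the WEKA-style configuration this design descends from;
both are plain arguments of `train_forest()`.

## Dataset curation rules

`build_windows()` turns FASTA sequences plus a site-annotation table into
labeled windows under these rules, each of which is a deliberate choice:

* **Every lysine is an instance.** Lysines reported modified are positive;
  in the default `assume_unmodified` mode every other lysine is negative.
  A site reported both modified and unmodified is treated as modified
  (experimental positives outrank absence-of-evidence negatives).
* **Windows at termini are padded, not dropped.** The padding symbol `X`
  encodes as the per-scale mean coefficient, which keeps dimensionality
  fixed without pulling the encoding towards any particular residue.
  Dropping terminal sites would silently discard annotated positives.
* **Redundancy removal is exact-duplicate removal** on the peptide string at
  the chosen window length. Similarity-threshold clustering (CD-HIT-style)
  changes the dataset in ways that depend on an arbitrary threshold and an
  external tool, so it is explicitly out of scope; the documented
  consequence is that near-identical homologous windows survive.
* **Class balancing** keeps all positives and a seeded uniform subsample of
  negatives of equal count. The seed is stored in the result so the exact
  dataset can be rebuilt.
* Non-standard residue codes (B, Z, U, O) are mapped to `X` with a warning
  rather than rejected, since they are common in real UniProt entries.

All external positions are 1-based; nothing in the API exposes a 0-based
offset.

## Evaluation battery

`compute_metrics()` reports sensitivity SN $= TP/(TP{+}FN)$, specificity
SP $= TN/(TN{+}FP)$, accuracy AC $= (TP{+}TN)/N$ (all as percentages) and
the Matthews correlation coefficient
$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP{+}FP)(TP{+}FN)(TN{+}FP)(TN{+}FN)}},$$
with the convention MCC $= 0$ when the denominator vanishes (the undefined
single-row/column case). Display rounding is two decimals; JSON reports also
carry the raw values.

Four protocols are provided. `percentage_split()` is a seeded uniform
shuffle followed by a prefix split of $\lfloor n \cdot p/100 \rfloor$
training instances — a deliberately simple, reproducible definition, since
"pick the most informative training instances" has no deterministic public
specification. `k_fold_cv()` partitions the shuffled index set into $k$
near-equal folds, tests each fold against a model trained on the rest, and
pools the confusion counts; stratification is available but off by default.
`loocv()` is `k_fold_cv` with $k = n$, and `self_consistency()` evaluates a
model on its own training set — the optimistic upper bound. ROC/AUC uses the
mid-rank Mann–Whitney statistic, which equals trapezoidal integration of
the ROC over all thresholds; every AUC in the test suite is cross-checked
against a brute-force count over positive–negative score pairs.
`window_sweep()` re-evaluates the same sites at windows 7/11/21 (narrow
windows are substrings of wide ones) under one shared seed.

## Motif analysis

`positional_frequency()` tabulates residue occurrences at each offset around
the center; padding symbols are excluded, so columns near the window edge of
a terminus-containing dataset sum to less than $n$. `matches_consensus()`
implements ΨKXE as: offset $-1$ in the hydrophobic set Ψ and offset $+2$
equal to `E`, with the center lysine guaranteed by the dataset invariant and
offset $+1$ unconstrained. The default Ψ is {A, F, I, L, M, P, V, W} — the
standard hydrophobic octet — and is configurable because the hydrophobicity
boundary is drawn differently across the literature (His is the marginal
case; we exclude it).

## The synthetic-data generators

The packaged count matrix (`table2_counts()`) gives, for each of the 21
offsets, how often each residue occurs among 293 curated modified-lysine
windows. Two generators build on it:

* `exact_marginal_dataset()` is deterministic: in each offset column the
  residues are laid out in fixed row order repeated by count, deficits up to
  $n$ are filled with `X`, and row $i$ across columns becomes peptide $i$.
  By construction its positional-frequency matrix equals the source matrix
  in every cell, which the tests verify by independent recount. Because the
  deficits of the curated matrix grow monotonically towards the window
  edges, the `X` symbols land contiguously at peptide ends, exactly like
  genuine terminus padding.
* `sample_positives()` draws each position independently from the
  column-normalized frequencies; `sample_negatives()` draws flanking
  residues i.i.d. uniform with a fixed central `K`. `make_benchmark()`
  combines 293 + 293 of these (the curated class composition) and encodes
  them with the packaged property table.

What the generator emulates is the *marginal* positional composition of
real modified sites: the glutamate enrichment at $+2$ (224/293 against a
1/20 background), the aliphatic preference at $-1$, the depletion of
tryptophan and cysteine throughout. What it deliberately does not emulate:
joint structure across positions (a count matrix carries no co-occurrence
information, so Ψ at $-1$ and E at $+2$ are sampled independently rather
than as a coupled motif), protein-level context, homology between windows,
and any realistic negative-set composition (real unmodified lysines are not
uniform background). Passing tests on this benchmark therefore demonstrate
that the pipeline learns and evaluates a positional-composition signal
correctly — not that the shipped defaults reach any particular accuracy on
real proteomes.

A consequence worth stating plainly: because positives are sampled from
marginals only, the two classes overlap, and even the Bayes-optimal
classifier on this generator misclassifies some windows. The small default
ensemble lands several points below that optimum on held-out folds, with
cross-validated accuracy in the high eighties and self-consistency around
ninety-nine percent; the test suite computes and tracks both on a fixed
seed. Larger ensembles narrow but do not close the gap. This is a property
of the study conditions (a marginal generator plus a ten-tree forest), not
a defect of the split search, which is verified node-for-node against an
exhaustive reference tree.

## Numerical and tie-breaking choices

* Split search: strictly smallest weighted Gini impurity wins; ties break
  to the lowest feature index, then the lowest threshold; a split must
  strictly decrease impurity or the node becomes a leaf. The brute-force
  oracle in the tests applies the same arithmetic in naive loops, so
  equivalence checks are exact, not tolerance-based.
* Leaf labels: majority class; an exact tie labels negative. Forest votes:
  positive iff the positive vote fraction exceeds 0.5, so a 5–5 vote is
  negative — a conservative rule for a site predictor, where a false
  positive costs wet-lab effort.
* Seeding: a master seed draws one sub-seed per tree (and per fold in
  cross-validation), so any component can be reproduced independently;
  every stochastic stage is a pure function of (inputs, seed).
* Feature-index tie-breaking means the decision function is permutation-
  invariant only when impurity minima are unique; the tests check the
  invariance on separable continuous data where that holds.
* The MCC zero-denominator convention, the `X`-as-mean padding rule, and
  the ARFF class ordering `{positive,negative}` are all fixed, documented
  constants rather than options.

## Problem sizes in the test suite

The suite runs the full-scale deterministic fixture (293 windows of length
21, all 420 frequency cells), a 586-instance encoded benchmark for the
learning checks (one self-consistency fit and one 10-fold cross-validation
of 10-tree forests at window 7), and dozens of small randomized datasets
(4–12 instances, 1–3 features) for the exhaustive oracle-equivalence
enumeration. These sizes were chosen to exercise every code path at the
curated study scale while keeping a full test run around a minute on one
core; the generators accept larger `n` for users who want tighter
law-of-large-numbers checks (the samplers are validated at $n = 10{,}000$
against 3-standard-error binomial bounds).

## Known limitations

* Exact-duplicate redundancy removal does not remove homologous
  near-duplicates; accuracy estimates on datasets with strong homology
  structure will be optimistic.
* The feature encoding treats positions independently; no pairwise or
  structural features are included, and the classifier must discover any
  interactions from data.
* The shipped defaults (10 trees, `mtry` $= \lfloor \log_2 M \rfloor + 1$)
  prioritize parity with the historical configuration over raw accuracy;
  users fitting real data should expect a larger ensemble to perform
  somewhat better and can set `n_trees` freely.
* The synthetic benchmark is a marginal model; results on it do not
  transfer quantitatively to real proteome-scale prediction.
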