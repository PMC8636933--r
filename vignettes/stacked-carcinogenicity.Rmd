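---
title: "Stacked-ensemble carcinogenicity prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked-ensemble carcinogenicity prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model, the
assumptions behind it, the parameters that matter, and the design decisions
taken where the method leaves room.

## The model

`carcstack` predicts a binary carcinogen/non-carcinogen call for small
molecules by stacked generalization. The hypothesis behind stacking is that
no single learning algorithm fits every region of chemical space, but
different algorithms err differently, so their combined opinions carry more
information than any one of them. The pipeline realizes this in two tiers:

- **Tier 1 (base classifiers).** Five classical algorithms — k-nearest
  neighbours, L2-regularized logistic regression, an RBF support vector
  machine with Platt-scaled probabilities, a random forest, and
  gradient-boosted trees — are each trained many times on independent
  random subsamples containing 80% of the training compounds (drawn without
  replacement within each subsample; a with-replacement bootstrap is
  available as a flag). Each member records its Matthews correlation
  coefficient (MCC) on the full training set and on the development set.
- **Selection.** Two rules prune each algorithm's population. The
  *original* rule keeps members whose development MCC lies in the central
  5–95 percentile band. The *supervised* rule keeps members whose MCC is
  strictly above the population mean on *both* sets; requiring both guards
  against members that fit the development set by luck.
- **Tier 2 (meta-classifier).** Every compound is re-represented by the
  vector of probabilities the selected members assign to it (the
  *model-level representation*). A small neural network — input width =
  number of selected members, one hidden layer of 10 ReLU units with batch
  normalization and dropout 0.5, a sigmoid output unit, binary
  cross-entropy loss, SGD with momentum — is trained on the development
  set's representation with the development labels, and is then applied to
  the test set's representation for the honest performance estimate.

MCC is the selection currency throughout because it is balanced: with 65%
carcinogens in the modelling data, accuracy rewards the trivial
all-positive classifier, while MCC (range −1 to 1, 0 = chance) does not.

## Data preparation

Compounds enter as SMILES (CSV/TSV) or SDF and are represented three ways:

- **MACCS keys** (computed natively): 166 substructure-presence bits. The
  package stores key *j* in column *j* with no dummy bit; the convention is
  recorded in the matrix metadata.
- **Substructure embeddings** (applied, not trained): a molecule's vector
  is the element-wise sum of its substructures' vectors from a
  user-supplied embedding table. Substructure identifiers are Morgan-style
  radius-0/1 atom-environment strings (element, plus the sorted
  bond-order/neighbour multiset). Out-of-vocabulary identifiers map to the
  table's `UNK` row when present, else to the zero vector — the common
  treatment for unseen vocabulary.
- **External descriptor tables** (ingested): any compounds × features CSV,
  e.g. 1D/2D physicochemical descriptor sets computed by outside software.

Preprocessing removes zero-variance descriptors, then scans columns left to
right and drops any column whose |Pearson r| with an earlier retained
column exceeds 0.9. Absolute correlation is used because an anti-correlated
descriptor is exactly as redundant as a correlated one; the keep-first scan
makes the surviving set deterministic and order-stable. Both choices are
configurable (`use_absolute`, `threshold`), and the comparison at the
threshold is strictly-greater. The two-step cleanup is idempotent.

The training/development/test split uses the Kennard–Stone max–min
algorithm: the first two selections are a maximally distant pair, and each
later selection maximizes its minimum Euclidean distance to the selected
set. The split is sequential — training selected from all compounds,
development by a second pass on the remainder, test as the residue — and
fully deterministic, with ties broken by lowest original index. The
mechanics of the second pass and the descriptor space used for distances
are genuinely open choices; the package defaults to the preprocessed
continuous representation and exposes the matrix as an argument, so any
representation can drive the split.

## Similarity analysis

To compare the discrimination power of representations, the package
computes within-class pairwise Tanimoto similarity: for continuous vectors
S = Σxy / (Σx² + Σy² − Σxy) (bounded in [−1/3, 1]), and for bit vectors
S = c / (a + b − c). On 0/1 vectors the two formulas coincide exactly. The
0/0 case (two all-zero vectors) is defined as 0 with a warning —
"no evidence of similarity" is the conservative reading — and only
unordered distinct pairs are counted. Whether similarities are computed on
raw or preprocessed descriptors is configurable; preprocessed is the
default since modelling happens there.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| subsample fraction | 0.8 | standard bagging fraction; each member sees most but not all compounds |
| search population | 100 per combination | enough draws for a stable mean dev-MCC per hyperparameter arm |
| final population | 1000 per algorithm | the supervised rule needs a large population for stable means |
| correlation threshold | 0.9 | conventional redundancy cut-off for QSAR descriptor sets |
| hidden units | 10 | the representation is already highly informative; a small head avoids overfitting the ~100-compound development set |
| dropout | 0.5 | strong regularization for a layer this small |
| SGD lr / momentum | 0.01 / 0.9 | conventional small-network settings |
| epochs / patience | 200 / 20 | early stopping on the monitored cross-entropy restores the best weights |
| batch size | 32 | conventional; batch statistics stay stable |
| heavy-molecule cutoff | 1000 Da | screening admissibility; beyond drug-like space |
| metal list | anything outside H,B,C,N,O,F,Si,P,S,Cl,Se,Br,I | flags organometallics/inorganics |

The SGD settings, epoch budget and early-stopping rule are this package's
own defaults — conventional small-network choices, recorded in the
persisted configuration for reproducibility — not published facts. The
layer order dense → batch-norm → ReLU → dropout is likewise a design
choice; the components are standard but their order is underdetermined.

## Numerical and degenerate-case choices

- A probability exactly at a decision threshold is a **positive** call,
  consistent with the average-probability consensus rule ("mean < 0.5 →
  negative, else positive"). Majority-vote ties are positive for the same
  reason.
- MCC with a zero denominator (e.g. everything predicted positive) returns
  0 with a warning; PPV/NPV with a zero denominator return `NA` with a
  warning.
- AUC is the Mann–Whitney rank statistic with ties counted ½.
- The chi-square in threshold prioritization is Pearson's without
  continuity correction by default (`correct = FALSE`); published p-values
  in this area rarely pin down the variant, so it is exposed and p-values
  should be read as descriptive.
- The 5–95 percentile band uses order statistics: the lowest
  `ceiling(0.05 n)` and highest `ceiling(0.05 n)` members mark the edges
  and values inclusively between the adjacent inner order statistics
  survive. With 100 distinct values 90 survive; an all-equal population
  survives entirely.
- A subsample missing a class is redrawn (bounded retries), then errors.
- KNN probability ties are resolved by the underlying vote with a pinned
  per-member seed, so populations replay exactly.

## The synthetic-data generator

`generate_synthetic()` emulates the *shape* of the modelling problem: 863
compounds at 65% positive (exactly 561/302 at the defaults), a binary
matrix of Bernoulli bits (fingerprint-like) and a continuous matrix of unit
variance Gaussians (embedding-like), with the first `n_informative`
features class-associated — a bit-probability gap for bits, a mean shift in
SD units for continuous features. The default effect size of 0.5 SD across
20 informative features makes the classes separable but noisily so, which
is the regime where stacking has something to add: individual base members
plateau while their errors decorrelate.

What the generator does **not** emulate: real descriptor correlation
structure, chemical clustering, scaffold effects, or label noise from
bioassay interpretation. Tests passing on synthetic data therefore
demonstrate that the machinery is correct and that the architecture adds
value when its assumptions hold — not that any particular real-world
performance level is reproduced. The published absolute numbers depend on
the curated compound list and external descriptor software and are out of
reach of an offline test; the package's acceptance checks instead verify
the worked-example arithmetic exactly and the stacking property
directionally (the meta-classifier's development MCC must exceed the
selected members' mean in at least 8 of 10 seeds).

Problem sizes used in the shipped checks — 20 members per algorithm rather
than 1000, fixed hyperparameter combinations rather than a grid search,
150 meta-epochs — were chosen so a full ten-seed study completes in about
a minute while preserving the phenomenon under test; all of them scale up
by configuration only.

## Known limitations

- The meta-classifier is trained and selected on the development set, so
  its development-set performance is in-sample; only the test-set numbers
  estimate generalization.
- Kennard–Stone splitting places the densest, most central compounds in
  the training set by construction; the resulting test set is *harder*
  than a random split, and specificity in particular suffers when the
  negative class is the minority.
- The screening filters are structural heuristics (element list, weight
  cutoff, InChIKey overlap); they do not assess applicability domain.
- Probability calibration of the sigmoid output is not enforced; the
  threshold-prioritization table is the intended instrument for choosing
  an operating point.
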