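---
title: "Predicting RNA m5C sites from sequence: models, encoders and design choices"
author: "m5Cpredict authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA m5C sites from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m5Cpredict)
```

## The problem

5-methylcytosine (m5C) is a post-transcriptional RNA modification in
which a methyl group is attached to the C5 atom of cytosine.
Experimental mapping is costly, so sequence-based classifiers are used
to score candidate cytosines. The local sequence context carries the
signal: a candidate site is represented as a window of λ = 20
nucleotides on each side of the cytosine, giving fixed 41-nt segments
over the alphabet {A, C, G, U}. Cytosines closer than λ to a transcript
end are skipped rather than padded — every encoder below assumes the
fixed width, and inventing flanking sequence would fabricate context.
DNA input is tolerated by mapping T to U, since the method is purely
composition based.

## Feature encoders

Seven families are concatenated into a canonical 808-column matrix, in
fixed block order with stable feature names (required so that rankings
round-trip through files):

* **ENAC (148)** — a window of S = 5 nt slides 5′→3′; each window
  contributes the four nucleotide frequencies (counts / S). Each
  window's four values sum to 1.
* **CKSNAP (96)** — for each gap k = 0…5, the 16 ordered pair
  frequencies of nucleotides k positions apart, normalized by the
  number of such pairs (L − k − 1). Each k-block sums to 1.
* **ANF (41)** — the accumulated nucleotide frequency
  d_i = (1/i) Σ_{j ≤ i} [S_j = S_i]: the prefix density of each
  position's own nucleotide. Values lie in (0, 1].
* **NCP (123)** — a 3-bit chemical-property code per position:
  A = (1,1,1), C = (0,1,0), U = (1,0,0), G = (0,0,1). The convention
  follows the fixed published tuples; note they do not coincide with
  the (purine, amino, strong-H-bond) class reading for U and G, but the
  encoding is a bijection either way and classifiers are indifferent to
  the labeling.
* **BIN (164)** — one-hot code per position (A, C, G, U order); every
  4-bit group sums to 1.
* **SCPseDNC (136)** — 16 normalized dinucleotide frequencies f_k plus
  λ·Λ weighted correlation factors. For tier m = 1…λ and property index
  ς = 1…Λ, θ_{m,ς} averages P_ς(R_iR_{i+1})·P_ς(R_{i+m}R_{i+m+1}) over
  i = 1…L−m−2, with Λ = 6 RNA dinucleotide step parameters (Roll, Rise,
  Shift, Twist, Slide, Tilt), z-standardized per index across the 16
  dinucleotides. All 136 components share the denominator
  Σf + w·Σθ (weight w = 0.9), so the vector sums to exactly 1. Two
  numerical choices were genuinely open: the upper summation bound per
  tier (we use L−m−2, the only choice consistent for both the first and
  last tier) and the Σθ range in the denominator (we use all λ·Λ terms,
  the only choice that normalizes the vector). The specific property
  values shipped in `inst/extdata` are the standard structural step
  parameters used throughout the pseudo-dinucleotide literature;
  because each index is z-standardized, moderate differences in the raw
  table shift individual SCPDNC values but never dimensions or the
  normalization.
* **W2V (100)** — segments are tokenized into overlapping 3-mers
  (stride 1, the dominant convention for nucleotide embeddings;
  configurable) and a continuous-bag-of-words embedding is trained on
  the training-split segments only — never on test segments, to avoid
  leakage. A segment's features are the mean of its token vectors,
  out-of-vocabulary tokens contributing zeros.

### The CBOW trainer

The embedding is trained in-package: with a 3-mer vocabulary of at most
4³ = 64 tokens, the exact softmax over the vocabulary is cheap, so the
model is the classic two-matrix CBOW (input embeddings averaged over a
±5-token context window, linear output layer, cross-entropy loss)
optimized by vectorized full-batch gradient descent (20 epochs,
learning rate 0.25 by default). Full-batch training with a seeded
initialization makes the vectors bit-reproducible, which the pipeline's
determinism contract requires; the embedding quality demands here are
modest (the W2V block is one of seven families and carries no planted
signal in the synthetic benchmark).

### A note on the ANF worked example

For the sequence `AUCUCAUGAG` the ANF definition gives
(1.00, 0.50, 0.33, 0.50, **0.40**, 0.33, 0.43, 0.13, 0.33, 0.20): the
value at position 5 is 2/5 because positions 1–5 contain two Cs (at 3
and at 5 itself). The tests assert this formula-consistent vector.

## Feature selection

Three rankers operate on the 808 columns:

* **Shapley ranking** — a gradient-boosted tree ensemble is fitted on
  the full matrix and every training row's per-feature attribution is
  computed exactly by the tree-path-dependent Shapley algorithm; a
  feature's score is the mean absolute attribution. The ranking model
  uses fixed hyperparameters (depth 6, learning rate 0.1, 500 trees,
  seeded) independent of any later per-dataset tuning, because ranking
  precedes hyperparameter search in the pipeline; importances come from
  one full-training fit rather than an average over folds. Attributions
  satisfy local accuracy (they sum, with the intercept, to the model's
  raw output) and are validated in the tests against a brute-force
  subset-enumeration Shapley oracle on stump ensembles.
* **F-score** — per feature, the squared separation of class means from
  the grand mean over the sum of within-class sample variances (n − 1
  denominators). Features with zero within-class variance but separated
  means get an infinite score and rank first.
* **mRMR** — features are discretized (equal-frequency quantile bins,
  5 by default; features with at most 5 distinct values are used as
  categories directly, so tied values never split across bins, which
  would otherwise correlate bin assignment with row order). Mutual
  information is estimated from the empirical joint histogram in nats.
  Selection is greedy: first the feature with maximal MI with the
  label, then repeatedly the feature maximizing relevance minus mean
  redundancy with the selected set. The returned ranking appends
  unselected features in relevance order (with NA scores) so it remains
  a permutation of all columns.

Ties are always broken by original column index; all three rankers are
deterministic given data and seed.

**Incremental selection** evaluates a grid of subset sizes n; for each
n the classifier is fitted on the top-n columns under stratified k-fold
cross-validation and the mean validation AUROC recorded. The optimal n
is the argmax (smallest on ties). The default grid steps by 4 up to 300
and by 20 thereafter — fine enough to localize the maximum, coarse
enough to stay cheap — and the fold seed is shared with the later
hyperparameter search so the two curves are comparable. Feature
selection is performed once on the training set rather than nested
inside each tuning fold; this follows the pipeline ordering of the
method family but carries a known optimistic bias for the selection
curve itself, which is why final evaluation uses out-of-fold
predictions of the tuned model.

## Classification and tuning

Folds are stratified: samples are assigned class by class in one global
round-robin after a seeded shuffle, so fold sizes differ by at most one
and every fold's class ratio is within one sample of the global ratio.
Plain random splitting can produce one-class folds on small sets
(benchmarks for some species have only a few hundred training rows),
which stratification rules out by construction.

Grid search is exhaustive by mean CV AUROC (the headline comparator
throughout), ties broken by grid order. The reference XGBoost grid —
8 depths × 5 learning rates × 7 tree counts = 280 combinations — is
provided as `xgbReferenceGrid()`; desk-scale runs default to a 2×2×2
corner grid (`xgbSmallGrid()`). Baselines: random forest (ranger; tree
count and depth tunable, per-fit seed) and RBF SVM (e1071; C and gamma
tunable, probability scores via the internal calibration). A single
top-level seed derives all stage seeds (simulation, embedding, ranking,
folds, final fit), so one integer reproduces a whole run.

## Evaluation

Counts use the rule score ≥ threshold (a score exactly at the threshold
is a positive call — this matters at ties and is fixed here so that
0.5 on a 0.5 score predicts positive). The scalar metrics are Sen, Spe,
Pre, Acc, F1, MCC and FOR = FN/(FN+TN). Zero-denominator conventions:
Pre = 0 when nothing is called positive, MCC = 0 when any denominator
factor vanishes, FOR = 0 when FN+TN = 0. The ROC area is computed by
trapezoids over distinct score cuts and equals the Mann–Whitney pair
statistic (ties counted one half); the PR area uses step-wise
summation, the standard for PR curves, since trapezoidal interpolation
overstates it. FPR-matched operating points take the smallest threshold
whose empirical FPR on the *training* calibration scores is at or below
the target — thresholds are never chosen on test data.

## The synthetic benchmark

`simulateSegments()` draws balanced sets of 41-nt segments i.i.d. from
a uniform background with the center fixed at C; in positives, each of
six designated positions (16, 18, 20, 22, 24, 26 by default) is drawn
from the mixture (1 − e)·background + e·δ(designated nucleotide). The
signal is planted positionally — not as motif k-mers — so the one-hot,
chemical-property and window-composition features provably carry it and
the generator can emit the exact ground-truth relevant columns
(`plantedFeatureNames()`): the one-hot indicators of the designated
nucleotides. At e = 0 the classes are identically distributed (the null
control); at e = 1 the designated nucleotides are deterministic. The
default study condition for acceptance runs is 500 + 500 segments at
e = 0.5, at which the planted one-hot columns are recovered by all
three rankers and the selected subset outperforms the full 808 columns;
test-scale runs use smaller sets (40–150 per class), sizes chosen so
the whole suite exercises every stage in a couple of minutes.

What the generator does *not* emulate: real methylome context (motif
structure around NSUN2/TRDMT1 targets, GC skew, species-specific
composition), redundancy between nearby sites, or class imbalance.
Passing tests therefore demonstrate that the machinery — encoding,
ranking, selection, tuning, thresholding — is correct and
self-consistent, not that any particular accuracy will transfer to real
benchmarks; real-data performance must be measured on real data via the
FASTA workflow.

## Known limitations

* The SCPseDNC property table is the standard published set, not
  necessarily the exact table used by any specific prior tool; values
  (not dimensions) of that block may differ between implementations.
* The CBOW trainer is word-level; it does not model sub-token character
  n-grams.
* mRMR mutual information depends on the discretization; the default
  5-bin equal-frequency scheme is documented and configurable but not
  adaptive.
* Feature selection is not nested within tuning CV (see above); the
  selection curve is an optimistic estimate of generalization.
```{r session}
sessionInfo()
```
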