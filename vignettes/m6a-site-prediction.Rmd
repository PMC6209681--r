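---
title: "Methods: sequence-based m6A site prediction with dinucleotide features and gradient boosting"
author: "m6apred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based m6A site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6apred)
```

## The problem

N6-methyladenosine (m6A) is the most abundant internal mRNA modification.
Peak-calling experiments locate methylated regions but not the exact
adenosine, so sequence-based classifiers are used to decide, for a candidate
adenosine, whether its local sequence context looks like a true site. The
unit of classification is a fixed-length window (typically 41, 51 or 101 nt,
always odd) centered on the candidate A; positives are windows centered on a
validated site, negatives are A-centered windows without a detected site, and
published benchmark sets are exactly class-balanced.

`m6apred` implements this pipeline end to end: window cleaning, two
positional dinucleotide descriptors, F-score + sequential-forward-search
(SFS) feature selection, a grid-searched gradient-boosted tree classifier,
and the field's evaluation protocols.

## Input handling and cleaning

`read_fasta()` normalizes records to uppercase RNA (`T` is mapped to `U`;
benchmark files circulate in both alphabets and the two letters share one
code in every descriptor, so nothing downstream changes).
`clean_sequences()` drops windows that (i) deviate from the declared window
length, (ii) contain any character outside `{A,C,G,U}` — degenerate IUPAC
codes are rejected rather than imputed, because both descriptors are defined
only over the four-letter alphabet — or (iii) lack the central adenosine.
The central-A check defaults to on for training data (both classes are
A-centered by construction) and can be disabled for bare prediction inputs.
Positions reported to users are 1-based.

## Feature descriptors

**Dinucleotide binary encoding (DBE).** Each of the `l - 1` overlapping
dinucleotides of a length-`l` window maps to a fixed 4-bit code, giving a
`4(l-1)`-dimensional 0/1 vector (160 dimensions at 41 nt). The code is the
concatenation of per-nucleotide 2-bit codes, first residue then second:

```{r code-table}
dinucleotide_code_table()
```

The per-nucleotide scheme A=00, U=01, C=10, G=11 is the unique assignment
consistent with the four anchor codes AA=0000, AU=0001, AC=0010, GG=1111
(the test suite proves uniqueness by enumerating all 24 assignments). The
mapping is a bijection, and DBE is injective over whole sequences: the
overlap chain determines every residue.

**Local position-specific dinucleotide frequency (LPSDF).** For positions
`i = 2..l`,

$$ f_i \;=\; \frac{C(X_{i-1}X_i)}{|N_i|}, $$

where `|N_i| = i` is the length of the `i`-th prefix `X_1..X_i` and `C`
counts the **overlapping occurrences of the dinucleotide `X_{i-1}X_i` within
that prefix**. The occurrence ending at `i` always counts, so `f_i` is in
`(0, 1)`. Two conventions deserve emphasis because the descriptor is often
described loosely:

* the denominator is the prefix length in residues (`i`), not the number of
  dinucleotides in the prefix (`i - 1`);
* the count is taken over the whole prefix, not only at position `i`. The
  per-position-only reading would make every `f_i` identically `1/i`,
  carrying no sequence information at all, which contradicts the
  descriptor's purpose.

Worked examples: `encode_lpsdf("AAAA")` is `(1/2, 2/3, 3/4)` and
`encode_lpsdf("ACGU")` is `(1/2, 1/3, 1/4)`.

`encode_dataset()` concatenates DBE then LPSDF (fixed order, recorded per
column), for `5(l-1)` features total — 200 at 41 nt. Features are used raw:
tree ensembles are invariant to monotone per-feature scaling, and no
standardization is applied.

## Feature selection

Features are ranked by the two-class F-score (the filter statistic, not the
F1 metric):

$$ F = \frac{(\bar x^{+}-\bar x)^2 + (\bar x^{-}-\bar x)^2}
           {\tfrac{1}{n^{+}-1}\sum_i (x_i^{+}-\bar x^{+})^2 +
            \tfrac{1}{n^{-}-1}\sum_i (x_i^{-}-\bar x^{-})^2}. $$

A feature constant within each class but different between classes (zero
denominator, positive numerator) is maximally discriminative and receives an
infinite sentinel score, ranking first; an everywhere-constant feature (0/0)
scores 0. Ties are broken by original column index, so the ranking is a
stable permutation.

`sfs_select()` then grows nested subsets along the ranking — size 1, 2, ...
up to `d` by default ("one by one"); a `stride > 1` coarsens the sweep for
wide matrices — and evaluates each subset by **pooled stratified
cross-validated accuracy under one fixed fold assignment** shared across all
subset sizes. Sharing the folds makes the comparison across sizes a paired
one, which is lower-variance than re-shuffling per size. The
accuracy-maximizing size wins; exact ties go to the smallest subset
(compact models preferred). A consequence worth knowing: when a single
top-ranked feature already attains the maximal accuracy — which happens
whenever the planted or biological signal is strong enough to be separable
on one coordinate — the selected subset is that single feature, by design.

Selection can run once on the full training set before the reported
cross-validation (`selection_mode = "flat"`, the reference protocol) or
inside every training fold (`"nested"`). Flat selection leaks information
from the evaluation folds into the feature choice and inflates the reported
performance, especially near the null; nested selection is leak-free and is
what the package's own null-control checks use. Both modes are exposed and
the flat default mirrors the reference protocol.

## Classifier and grid search

The classifier is consumed through a minimal contract — `trainer(x, y)`
returns a scoring closure emitting class-1 probabilities — and the default
backs it with xgboost (binary logistic objective, single thread). Two
defaults differ from the library's: exact greedy split finding instead of
histogram binning, and no minimum-hessian leaf constraint
(`min_child_weight = 0`). Both are small-data fidelity choices: the
benchmark datasets have only hundreds to a few thousand windows, where
histogram bin edges sit exactly on training extremes (misclassifying
held-out boundary points) and the default hessian floor prevents any split
on the tiny training sets that arise under jackknife evaluation. Complexity
is still controlled by depth, shrinkage and the L2 penalty.

`grid_search_train()` exhaustively evaluates a grid — defaults: `max_depth`
2..10, learning rate 0.1..0.8 in steps of 0.1 (the reference range gives
only the endpoints; 0.1 is the natural step), boosting rounds 1..10 — by
pooled stratified CV accuracy under one fixed fold assignment, breaks ties
toward (fewer rounds, shallower trees, smaller learning rate) so the result
is invariant to enumeration order, and refits the winner on all rows. The
1..10 round range is honored as the reference default but is unusually small
for gradient boosting; pass e.g. `n_estimators = c(50, 100, 200)` for real
use. The decision threshold is fixed at 0.5 (a score of exactly 0.5 is
called a site); ROC analysis sweeps thresholds independently.

All stochasticity — fold shuffling everywhere, tree construction — derives
from one user-supplied master seed; identical seeds reproduce selection
traces, tuned parameters and predictions bit-for-bit.

## Evaluation protocols

`compute_metrics()` evaluates the standard formulas exactly: `Sn =
TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/n`, `MCC = (TP·TN − FP·FN) /
√((TP+FN)(TN+FP)(TP+FP)(TN+FN))`, with MCC = 0 when its denominator
vanishes and `NaN` plus a warning for a rate whose class is absent. Values
are fractions internally; the CLI and `metrics_json(percent = TRUE)` render
the ×100% convention.

`roc_auc()` sweeps the threshold over distinct scores (ties cross
simultaneously) and integrates trapezoidally, which equals the normalized
Mann–Whitney pair count with ties worth 1/2 — the suite asserts this
equivalence against a brute-force pair-counting oracle and against pROC.

`cross_validate()` (stratified folds; all four benchmark shapes are exactly
class-balanced, which stratification preserves per fold) **pools** the
out-of-fold predictions into one confusion table and one score vector
rather than averaging per-fold metrics: published results report single
values per protocol without fold variances, and pooling degenerates cleanly
to the jackknife definition. `jackknife()` is leave-one-out with the same
pooling; it refuses `n` above a configurable cap (default 5000) without
`force = TRUE`, since it trains `n` models.

## Synthetic benchmark generator

`generate_synthetic()` emulates the *structure* of the benchmark datasets:
equal-sized classes, odd window length, central adenosine forced in both
classes (negatives are A-centered non-sites by construction). Positives
optionally carry planted signal: a motif (default `GAC`, echoing the
DRACH-like consensus with the methylated A centered; the motif's A is
aligned with the window center so the central A is never overwritten)
written with probability `motif_probability`, plus optional per-position
dinucleotide plantings (`positional_bias`, each entry a dinucleotide, its
1-based end position, and a planting probability). Signal is planted at the
dinucleotide-positional level deliberately: both descriptors are
dinucleotide-positional, so recovery tests exercise exactly the feature
space the encoders span. Background residues are i.i.d. from a configurable
distribution (default uniform).

What the generator does **not** emulate: real m6A context statistics
(degenerate DRACH variants, positional nucleotide skews around sites),
transcript-level composition, or correlated negatives drawn from the same
transcripts. Passing tests therefore demonstrate that the machinery
recovers dinucleotide-positional signal at realistic sample sizes — not
that any particular accuracy will be attained on biological data.

## Problem sizes and numerical choices

The shipped checks run at deliberately modest sizes chosen to exercise the
full pipeline while keeping the suite quick: selection-recovery benchmarks
use n = 400 with 100 features; end-to-end monotonicity uses 200+200 windows
of 41 nt at motif probabilities 0, 0.5 and 1 under nested 10-fold CV; the
acceptance script evaluates the full default grid (720 points) on 200+200
windows. Degenerate inputs are handled explicitly: empty FASTA files,
all-rejected cleaning, single-class label vectors, matrices with one
column, and corrupted or version-mismatched model bundles all raise
structured errors naming the cause.

## Known limitations

* The flat selection protocol's leak (above) is inherent to the reference
  procedure; use `"nested"` when an unbiased estimate matters.
* The SFS smallest-subset tie-break means strongly separable signals yield
  very small selected subsets; the full accuracy trace is always returned
  for inspection.
* Only the two shipped descriptors are implemented; physicochemical and
  pseudo-composition encodings are out of scope.
* The tool consumes pre-windowed sequences; it does not scan transcripts to
  extract candidate windows.
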