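---
title: "Fuzzy nearest-neighbor imputation: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy nearest-neighbor imputation: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fknnimpute)
```

## The imputation model

Missing cells in a numeric table are usually handled by deletion (dropping
incomplete rows) or by single-value imputation (the column mean or median).
Both discard information: deletion throws away the observed parts of
incomplete rows, and a single fixed value ignores that some observations are
far more similar to the incomplete one than others. `fknnimpute` implements
a local, similarity-weighted alternative: for each missing cell it finds the
k complete-case observations closest to the incomplete row and replaces the
cell by a weighted average of their values in the target column, with
weights given by a fuzzy membership function fitted to the neighbor value
set.

For a missing cell in row $r$, column $j$:

1. **Neighbor selection.** Candidate rows are those observed at column $j$
   and at every *distance column* — all feature columns other than $j$,
   restricted to the columns where row $r$ is itself observed (a
   pairwise-available rule that keeps multiply-missing rows imputable).
   Each candidate's Euclidean distance to row $r$ over the distance columns
   is computed, and the $k$ smallest are kept; exact ties prefer the lower
   row index so results are deterministic.
2. **Membership fit.** The $k$ neighbor values $X = \{x_1, \dots, x_k\}$
   in column $j$ parameterize a fuzzy set. The *triangular* form uses
   $(a, b, c) = (\min X, \bar X, \max X)$ with

   $$\mu(x) = \begin{cases} 0 & x \le a \\ (x-a)/(b-a) & a < x \le b \\
   (c-x)/(c-b) & b < x < c \\ 0 & x \ge c \end{cases}$$

   The *Gaussian* form uses the mean $\mu$ and the population standard
   deviation $\sigma$ of $X$ with
   $\mu(x) = \exp\!\left(-(x-\mu)^2 / 2\sigma^2\right)$.
3. **Weighted average.** The imputed value is
   $\sum_i x_i\,\mu(x_i) \big/ \sum_i \mu(x_i)$, which always lies inside
   the neighbor value range.

Every cell is imputed against the *original* matrix: freshly imputed values
never enter later neighbor searches, so the result is independent of the
order in which cells are processed and the whole operation is a pure
function of the input.

### Why the population standard deviation

The Gaussian width is the population form $\sigma =
\sqrt{\tfrac1k \sum_i (x_i - \bar X)^2}$, not the sample form with divisor
$k-1$. The membership function here describes the spread of the neighbor
set itself — a complete, known collection of $k$ values — rather than
estimating the dispersion of a larger population from a sample, so the
divisor-$k$ form is the coherent choice. For the illustration set
$\{2, 1, 7\}$ it gives $\sigma \approx 2.6247$ and the weights
$0.8790 / 0.6736 / 0.3769$ shown in the package examples.

### Degenerate cases

The weight formulas are undefined or uninformative in three situations, and
the imputer resolves each through a fixed fallback chain rather than
failing (every invocation is logged by the command-line tool):

* **All neighbor values identical** — that value is imputed directly (it is
  the only value the weighted average could produce).
* **All triangular weights zero** (every neighbor value sits at the set's
  minimum or maximum, e.g. $k = 2$), or **zero Gaussian spread** — the
  arithmetic mean of the neighbor values is imputed. The formulas define no
  weights here, and the unweighted mean is the neutral completion.
* **No eligible candidate row** — the column mean of the observed values is
  imputed. A column with no observed values at all is an error.

With $k = 1$ the single neighbor's value is returned under both membership
kinds (a one-point set falls under the first rule).

### Boundary conventions

The triangular branches are implemented exactly as written above: the
minimum and maximum of the neighbor set always receive weight 0, including
the boundary points $x = a$ and $x = c$, and the peak value $b$ receives
weight 1. Degenerate branches ($b = a$ or $c = b$) evaluate to 0 instead of
dividing by zero. The Gaussian membership uses the true exponential
function; in double precision it can underflow to exactly 0 for points very
far from the center, which the weighted average treats as any other zero
weight.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 3 | neighbors per missing cell; the benchmark sweeps {3, 5, 7, 9} |
| `membership` | `"triangular"` | weighting kernel: triangular or Gaussian |
| `include_label` | `FALSE` | whether the class label joins the distance |
| `train_fraction` | 0.8 | stratified train share in the benchmark |
| missing markers | `""`, `"NA"`, `"?"` | cell contents read as missing |

Small `k` keeps the neighborhood local (low bias, higher variance); the
{3, 5, 7, 9} sweep in `run_benchmark()` covers the useful range for tables
of a few hundred to a few thousand rows. The class label is excluded from
distances by default because at imputation time the label plays the role of
the prediction target and letting it shape the imputation would leak label
information into the features; `include_label = TRUE` is available for
settings where the label is legitimately part of the observation.

## The evaluation harness

`run_benchmark()` scores missing-data handlers by downstream classification
accuracy, the criterion a practitioner ultimately cares about: handle the
missing data, split the rows into stratified train/test sets (80/20 by
default), min–max normalize with parameters fitted on the training split
only, fit a classifier, and compute held-out accuracy
$\mathrm{Acc} = (TP + TN)/(TP + TN + FP + FN) \times 100$ from the
confusion matrix. Four classifiers are included, each delegated to an
established library: Euclidean k-nearest-neighbor classification
(`class::knn`, k = 5), Gaussian naive Bayes (`e1071::naiveBayes`), a
decision tree (`rpart::rpart`, default pruning), and a single-hidden-layer
perceptron (`nnet::nnet`, 8 hidden units, weight decay 0.01, 200
iterations, the scale at which such a net fits tables of this width
stably). Classifier hyperparameters are deliberately ordinary defaults —
the object of comparison is the imputer, not the classifier.

Two design points are worth making explicit:

* **Imputation precedes the split.** The pipeline imputes the full table
  and then splits, mirroring the workflow the method targets (a dataset is
  completed once, then used). Neighbor imputation therefore sees rows that
  later land in the test split; accuracies compare imputers under identical
  conditions but are not leakage-free estimates of deployment accuracy.
  Normalization, by contrast, is fitted on the training split only.
* **Shared partitions.** For a given classifier, every imputer is scored on
  the same seeded stratified split, so grid cells differ only in the
  quantity under study. A repeated run with the same seed is identical; a
  cell that cannot run (listwise deletion emptying a class, or the `none`
  handler leaving the table incomplete) is reported as failed rather than
  aborting the grid.

A single stratified split (rather than cross-validation) is the default
because the benchmark's purpose is ranking handlers under identical
conditions; repeated runs across seeds are available by calling
`run_benchmark()` in a loop with different `seed` values and pooling the
results with `summarize_benchmark()`.

## What the synthetic generator does and does not emulate

`generate_synthetic()` draws a binary label (Bernoulli, default balance
0.5) and, conditional on the class, independent unit-variance Gaussian
features whose class means differ by `effect_size` (default 2) standard
deviations. This emulates the shape of the public classification tables the
method targets — a few hundred rows, around ten numeric features, a binary
label — and gives the features exactly the property neighbor-based
imputation exploits: marginal between-feature correlation induced by the
class structure, which unconditional column means cannot use.
`inject_mcar()` then blanks a chosen fraction of feature cells (5% and 10%
are the conventional study points) uniformly at random, never touching the
label and never emptying a whole row.

What it does **not** emulate: within-class feature correlation, skewed or
heavy-tailed marginals, mixed scales, categorical features, and
informative (MAR/NMAR) missingness. Passing tests on this generator
demonstrate correctness of the algorithms and the directional advantage of
neighborhood information under MCAR; they do not certify accuracy gains on
any particular real dataset.

The packaged simulation checks run at sizes chosen to exercise the method
meaningfully while keeping the default test run quick: the
parameter-recovery study uses 20 replicates of a 500 × 10 table with 5%
MCAR (fuzzy-KNN mean restoration RMSE must not exceed mean-imputation
RMSE), and the end-to-end benchmark reproducibility check uses a 150 × 6
table. Users studying their own settings can scale all of these up freely.

## MCAR injection protocol

How missingness is injected is itself a design decision. `inject_mcar()`
interprets the proportion as a fraction of *feature cells* (not rows),
draws exactly `round(proportion * n_cells)` distinct cells uniformly
without replacement, and enforces that no row loses all of its feature
values (a fully blank row has no distance information at all and would only
measure the column-mean fallback). The implementation visits cells in a
seeded random order and skips any cell whose removal would empty a row;
infeasible requests error rather than silently delivering fewer cells.

## Known limitations

* Distances are Euclidean over raw feature scales; features measured on
  very different scales will dominate the neighbor search unless the user
  rescales first. (Normalization inside the benchmark happens after
  imputation, matching the pipeline the harness models.)
* Only numeric features are supported; categorical distance metrics,
  chained/iterative imputation and MAR/NMAR-aware estimation are out of
  scope.
* Neighbor search is exact and quadratic in the worst case; tables beyond
  roughly 10^4 rows with heavy missingness will be slow.
* The confusion-matrix accuracy is defined for binary labels; multiclass
  benchmarks fall back to overall agreement.
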