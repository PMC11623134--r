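---
title: "Encoding categorical predictors and out-of-bag leakage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding categorical predictors and out-of-bag leakage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`leakyforest` exists to make one mechanism visible: when categorical
predictors are ordinal-encoded with a *target-based* method, and the encoding
is fitted on the full training set *before* bagging, the response values of
every row — including rows that later fall out of bag — are baked into the
predictor column that each tree splits on. The out-of-bag sample then stops
behaving like held-out data. This vignette records the model, the knobs, and
the design decisions, so that the simulation results the package produces can
be read with the right caveats.

## The model

The classifier is a standard bagged ensemble of CART classification trees:

* each tree is grown on a bootstrap sample of the training rows (`n` draws
  with replacement; the roughly `(1 - 1/n)^n ≈ 37%` of rows never drawn are
  that tree's OOB set);
* at each node, `mtry` candidate variables are drawn without replacement and
  the split maximising the Gini impurity decrease
  `ΔG = G(parent) − (n_L/n) G(left) − (n_R/n) G(right)` over midpoint
  thresholds of the encoded values is taken;
* nodes are split until pure or unsplittable (`min_node_size = 1`, no depth
  limit), leaves predict their in-bag majority class;
* the forest predicts by majority vote; the OOB prediction of a row
  aggregates only trees for which the row was OOB.

Predictors are purely categorical. Before any tree sees them they pass
through a `level_encoding`, a bijection from observed levels to ranks
`1..k`. Three methods are implemented:

* `integer_alpha` — lexicographic (C byte order) on the level label;
  target-agnostic by construction;
* `target_twoclass` — ascending within-level proportion of the second
  class; for two classes, threshold splits on this ordering attain the same
  optimum as exhaustive search over all `2^(k-1) − 1` level bipartitions
  (the test suite verifies this against a brute-force enumeration);
* `target_pca` — ascending projection of the per-level class-probability
  vectors onto the leading eigenvector of their weighted covariance matrix;
  the multiclass generalisation of the same idea.

`encoding_timing` decides what data the encoder may see:
`before_bagging` fits one encoding per variable on the full training set
(every tree shares it — the computationally cheap and, for target-based
methods, leaky variant), `after_bagging` refits the encodings of every tree
on its own bootstrap sample, multiplicities included, so the tree's OOB rows
are untouched.

## Parameters that matter

* `n_trees` (default 500): the study conditions use 500 trees at full scale;
  the test suite uses 200, which keeps Monte-Carlo noise on OOB/test error
  means well inside the tolerances it asserts.
* `mtry` (default `ceiling(sqrt(p))`): with a single predictor the only
  coherent value is 1, which is what the single-variable simulations use.
* `min_node_size` (default 1): trees grown to purity, the classification
  default in this family of methods. Larger values blunt the leakage signal
  because deep, nearly-singleton nodes are where a response-informed
  ordering pays off most.
* `absent_policy` (default `majority_child`): levels unseen at encoding time
  become a missing sentinel that split search excludes from threshold
  enumeration and routing sends to the child with more in-bag samples (ties
  left). After-bagging and per-fold encodings meet absent levels routinely,
  so the strict (erroring) policy is retained only for debugging.
* `seed`: one master seed; per-tree seeds are drawn from it, and tree
  growth uses its own deterministic generator (a fixed Mersenne Twister with
  modulo draws rather than a distribution adapter, so results do not depend
  on the C++ standard library). Identical inputs give bit-identical
  forests, predictions and split records.

## The importance measures

**MDI** sums `n_node × ΔG` over the nodes split on a variable and averages
over trees. It is reported on the classical unnormalised scale — a node with
`m` in-bag samples contributes `m · ΔG` — so values grow with sample size.
Per tree, the totals conserve the impurity budget: in-bag size times (root
impurity minus the leaf-impurity mixture), which the tests check to 1e-9.
Under null data MDI is *positive* for every encoding: greedy splitting
always purifies the in-bag sample, and more levels mean more thresholds.
It measures structure used, not generalisable signal.

**MDA** permutes a variable within each tree's OOB rows and averages the
error increase, unscaled (no SD normalisation). One permutation per
(tree, variable) from a seeded stream; a forced identity permutation gives
exactly zero, which pins the implementation down.

**AIR** (actual impurity reduction) corrects MDI by subtraction: each tree is
grown over the real variables *plus one permuted copy of each*, and the
AIR of a variable is its MDI-style sum minus the same sum for its copy. Two
choices here were genuinely open, and we settled both by requiring the
measure to be exactly null-centred:

* *What the permuted copy is.* A permutation of the training rows applied to
  the encoded column, drawn per (tree, variable), and read *through* the
  bootstrap — all bagged copies of one row share one shadow value, exactly
  as they share one response. Permuting the in-bag rows directly (with or
  without multiplicity) breaks that coupling and makes the null mean drift
  by several per cent of the MDI scale in either direction.
* *Where the copy is scored.* The copies compete for splits as ordinary
  candidate variables. Under a null response, real column and permuted copy
  are then exchangeable at every step of the recursion, so their decrease
  sums have identical distributions and the difference is centred at zero —
  a symmetry no evaluate-only bookkeeping (scoring the copy at nodes the
  real variable won) can deliver, because the recursion itself is driven by
  the real columns. The cost is that an AIR forest is grown for AIR:
  `run_experiment()` fits a separate shadow-free forest for error metrics,
  and prediction data without shadow values routes those splits like absent
  levels.

**Holdout / Independent Holdout** split the data into two random folds,
train a forest per fold, and average each variable's permutation importance
computed on the opposite fold (every tree scores the entire opposite fold).
The two variants differ in exactly one line: Holdout fits the level
encodings once on the pooled data before the fold split — so a target-based
encoding leaks across folds even though no OOB data is used — while
Independent Holdout fits them inside each fold and encodes the opposite fold
through that map, absent levels per policy. Folds are an unstratified
random half/half; the package errors if a fold ends up single-class rather
than silently degrading.

## The null generator, and what it does not emulate

`generate_null_dataset()` draws each of `p` predictors i.i.d. uniformly from
`k` levels, the response i.i.d. uniformly from three classes, and an
unstratified 80/20 train/test split — the balanced, signal-free design under
which every honest error estimate is 2/3 and every honest importance is
zero, so any deviation is bias by construction. The full-scale grid is
`n ∈ {20, 50, 100, 150, 200, 400}` × `k ∈ {1, 5, 10, 35, 50, 100, 150, 200}`
with 99 replicates of 500 trees; `simulation_config()` defaults to it, and
the test suite runs reduced profiles (20 replicates, 200 trees, two or three
grid cells per claim) chosen so each property is separated by several
standard errors while the whole suite stays in the minutes range.

Deliberate simplifications: levels are uniformly frequent (real categorical
data is long-tailed, which strengthens the absent-level pathway); classes
are balanced (imbalance interacts with majority-vote tie-breaking and with
small test sets — the `n = 20` cells are noisy for exactly that reason);
predictors are mutually independent; and there is no true signal, so the
simulations bound bias under the null but say nothing about how much of a
*real* variable's measured importance is leakage. Passing tests demonstrate
the mechanism and its repair, not the magnitude of either on any particular
real dataset.

## Numerical choices and degenerate inputs

* All orderings break ties lexicographically on the level label, in C byte
  order (`"10" < "2"`), so fits are locale-independent and reproducible.
* The `target_pca` eigenvector's sign is fixed by making its first nonzero
  coordinate (in class order) positive; flipping it merely reverses ranks,
  which threshold splits are invariant to. A zero covariance matrix (all
  levels sharing one class profile, or a single level) falls back to
  lexicographic order. Encoded values are the ranks themselves, not raw
  projection scores — outcome-equivalent for threshold splits and free of
  floating-point coincidences.
* Split ties break to the lower variable index, then the smaller threshold;
  vote and leaf ties to the first class in class order. Under the null this
  is bias-free because the class order never depends on the data-generating
  process.
* `k = 1` predictors are encodable (a single rank) and simply never yield a
  valid split: simulation cells with `k = 1` report majority-vote error
  rates and exactly zero for every importance measure.
* Gini conservation holds to 1e-9 per tree; the two-class
  bipartition-equivalence check runs at 1e-9; probability vectors are
  validated to 1e-12 at encoding time.

## Known limitations

Only classification with categorical predictors is supported — no numeric
predictors, regression, survival, class weights, or probability forests.
The two-class within-node re-encoding some implementations use, and one-hot
or distance-based encodings, are out of scope. Holdout importance always
uses two folds. Forests store their training data and per-tree records to
keep every diagnostic recomputable; for the simulation scales this package
targets (hundreds of rows) that is cheap, but it is not engineered for
large-scale production use.
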