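# leakyforest

Random forests for categorical predictors, with explicit control over **how**
levels are ordinal-encoded and **when** the encoding is fitted — plus the
out-of-bag (OOB) and variable-importance machinery needed to see why that
choice matters.

## The problem

Random forest implementations routinely turn a nominal predictor with levels
`{a, b, c, ...}` into an ordered numeric column before growing trees.
Target-*agnostic* encodings (e.g. alphabetical integer encoding) never look at
the response. Target-*based* encodings do: with two classes, levels are
ordered by the within-level proportion of the second class; with more
classes, by the projection of each level's class-probability vector
`p_l = (n_{l1}, ..., n_{lC}) / n_l` onto the first principal component of the
weighted covariance matrix

```
Σ = Σ_l w_l (p_l − p̄)(p_l − p̄)ᵀ,   w_l = n_l / n,   p̄ = Σ_l w_l p_l .
```

Target-based orderings are attractive — for two classes an ordered threshold
search recovers the best of all `2^(k−1) − 1` level bipartitions — but when
the encoding is fitted once on the **full training set before bagging**, every
tree's out-of-bag rows have already contributed their response values to the
encoding. The OOB sample is no longer an honest test set: under pure noise,
OOB error drops well below the true misclassification rate and
permutation-style importances inflate above zero. Fitting the encoding
**after bagging** — independently on each bootstrap sample — removes the
leak, as does evaluating on truly independent data.

`leakyforest` implements the full pipeline from scratch so every piece is
inspectable: ordinal encoders with recorded fit provenance and absent-level
policy, bagged CART trees with Gini splitting (`Gini = 1 − Σ_c p_c²`,
in-bag/OOB bookkeeping, per-node split records), OOB and test error, five
variable-importance measures —

| measure | evaluation data | leaks under before-bagging target encoding? |
|---|---|---|
| MDI (mean decrease in impurity) | in-bag | no (but inflated under the null regardless of encoding) |
| MDA (permutation importance) | OOB | yes |
| AIR (actual impurity reduction, via competing permuted copies) | in-bag vs permuted copy | yes |
| Holdout (two cross-validation folds, pooled encoding) | opposite fold | yes |
| Independent Holdout (encodings fitted per fold) | opposite fold | **no** |

— and a null-simulation engine (`generate_null_dataset()`,
`run_experiment()`, `summarize_experiment()`) that measures all of the above
on data with *no* predictor–response relationship.

## Worked example

52 training rows, one predictor with up to 100 levels, three equiprobable
classes, no signal whatsoever:

```r
library(leakyforest)

ds <- generate_null_dataset(n = 65, k = 100, p = 1, n_classes = 3, seed = 42)
train <- ds$data[ds$train_idx, ]
test  <- ds$data[ds$test_idx, ]

for (enc in c("integer_alpha", "target_pca")) {
  params <- forest_params(n_trees = 500, seed = 7, encoding_method = enc,
                          encoding_timing = "before_bagging")
  forest <- fit_forest(train, "y", params)
  cat(sprintf("%-14s  OOB error: %.3f   test error: %.3f\n",
              enc, oob_error(forest), test_error(forest, test)))
}
#> integer_alpha   OOB error: 0.731   test error: 0.615
#> target_pca      OOB error: 0.308   test error: 0.692
```

The true error of any classifier here is 2/3. Alphabetical encoding is
honest on both estimates; the target-based encoding fitted before bagging
reports a spectacular-looking 0.308 OOB error while the withheld test set
still (correctly) sees noise. The importance measures tell the same story:

```r
params <- forest_params(n_trees = 500, seed = 7, encoding_method = "target_pca")
forest <- fit_forest(train, "y", params)
mda_importance(forest, seed = 1)$values                                  # 0.348
holdout_importance(train, "y", params, seed = 1)$values                  # 0.392
holdout_importance(train, "y", params, seed = 1,
                   encode_per_fold = TRUE)$values                        # 0.019
```

A variable with zero predictive content scores 0.35–0.39 under OOB
permutation and pooled-encoding holdout importance; only the Independent
Holdout — encodings fitted separately inside each fold — stays at zero.
Refitting the encoding on every bootstrap sample repairs the OOB estimate:

```r
repaired <- fit_forest(train, "y",
  forest_params(n_trees = 500, seed = 7, encoding_method = "target_pca",
                encoding_timing = "after_bagging"))
oob_error(repaired)
#> 0.673
```

## Command line

`exec/leakyforest` wraps the same functions:

```sh
leakyforest fit        --input data.csv --encoding target_pca --timing before --out results/
leakyforest importance --input data.csv --methods MDI,MDA,AIR --trees 500 --seed 1 --out results/
leakyforest simulate   --config config.yaml --out results/
```

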