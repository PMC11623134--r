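#' Variable-importance result container
#'
#' @param method one of `"MDI"`, `"MDA"`, `"AIR"`, `"Holdout"`,
#'   `"IndependentHoldout"`.
#' @param values named numeric vector, one score per predictor.
#' @param n_trees_used trees contributing to the mean.
#' @param rng_seed seed of the permutation stream (`NA` for deterministic
#'   measures).
#' @return An object of class `importance_result`.
#' @keywords internal
new_importance_result <- function(method, values, n_trees_used,
                                  rng_seed = NA_integer_) {
  structure(list(method = method, values = values,
                 n_trees_used = n_trees_used, rng_seed = rng_seed),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat("<importance_result> ", x$method, " (", x$n_trees_used, " trees)\n",
      sep = "")
  print(x$values)
  invisible(x)
}

#' Out-of-bag misclassification rate
#'
#' Fraction misclassified among training rows that have an OOB prediction
#' (rows never out of bag are excluded from the denominator).
#'
#' @param forest a `leaky_forest`.
#' @return Error rate in `[0, 1]`.
#' @export
oob_error <- function(forest) {
  pred <- oob_predict(forest)
  truth <- as.character(forest$train[[forest$response]])
  keep <- !is.na(pred)
  if (!any(keep)) stop("no training row has an OOB prediction")
  mean(pred[keep] != truth[keep])
}

#' Misclassification rate on an independent test set
#'
#' @param forest a `leaky_forest`.
#' @param test data.frame with the forest's predictors and response column.
#' @return Error rate in `[0, 1]`.
#' @export
test_error <- function(forest, test) {
  if (nrow(test) == 0L) stop("empty test set")
  pred <- predict(forest, test)
  mean(pred != as.character(test[[forest$response]]))
}

# Per-tree sums of node-size-weighted impurity decrease over nodes split on
# each column (the scale classical impurity importances are reported on: a
# node with m in-bag samples contributes m * decrease, so values grow with
# sample size). Forests grown for corrected impurity carry 2p columns (real
# variables then their permuted copies).
tree_weighted_sums <- function(forest) {
  p <- length(forest$vars)
  p_tot <- if (forest$params$air_shadows) 2L * p else p
  m <- vapply(forest$trees, function(tr) {
    nd <- tr$nodes
    internal <- nd$split_var > 0L
    out <- numeric(p_tot)
    if (any(internal)) {
      contrib <- nd$n_node[internal] * nd$decrease[internal]
      s <- tapply(contrib, nd$split_var[internal], sum)
      out[as.integer(names(s))] <- s
    }
    out
  }, numeric(p_tot))
  matrix(m, nrow = p_tot) # vapply drops to a vector when p_tot = 1
}

#' Mean decrease in impurity (Gini importance)
#'
#' For each variable, the mean over trees of the sum of
#' `n_node * impurity_decrease` over the nodes that split on it, evaluated
#' on the in-bag samples (so a tree's scores sum to the in-bag size times
#' the impurity budget it spent). Nonnegative by construction; under null
#' data it is inflated for variables with many levels — and grows with
#' sample size — because every greedy split still purifies the in-bag
#' sample.
#'
#' @param forest a `leaky_forest`.
#' @return An `importance_result`.
#' @export
mdi_importance <- function(forest) {
  p <- length(forest$vars)
  m <- tree_weighted_sums(forest)[seq_len(p), , drop = FALSE]
  new_importance_result("MDI",
                        stats::setNames(rowMeans(m), forest$vars),
                        length(forest$trees))
}

#' Permutation importance (mean decrease in accuracy)
#'
#' For each tree and variable, the variable's encoded column is permuted
#' within the tree's OOB rows and the tree's OOB error recomputed; the score
#' is the mean over trees of (permuted error - original error), unscaled.
#' One permutation is drawn per (tree, variable) from the seeded stream.
#'
#' @param forest a `leaky_forest`.
#' @param seed integer seed for the permutation stream.
#' @param identity_permutation use the identity instead of a random
#'   permutation (diagnostic; yields exactly zero for every variable).
#' @return An `importance_result`.
#' @export
mda_importance <- function(forest, seed = 1L, identity_permutation = FALSE) {
  p <- length(forest$vars)
  truth <- as.character(forest$train[[forest$response]])
  shared_X <- if (!is.null(forest$shared_encodings))
    encode_data(forest$shared_encodings, forest$train, forest$vars)
  set.seed(seed)
  used <- 0L
  acc <- numeric(p)
  for (t in seq_along(forest$trees)) {
    oob <- forest$trees[[t]]$oob
    if (length(oob) == 0L) {
      warning("tree ", t, " has an empty OOB set; skipped")
      next
    }
    X <- if (is.null(forest$trees[[t]]$encodings))
      shared_X[oob, , drop = FALSE]
    else
      encode_data(forest$trees[[t]]$encodings,
                  forest$train[oob, , drop = FALSE], forest$vars)
    y_oob <- truth[oob]
    cls <- forest$class_order
    err0 <- mean(cls[predict_tree_cpp(forest$trees[[t]]$nodes, X)] != y_oob)
    for (j in seq_len(p)) {
      perm <- if (identity_permutation) seq_along(oob)
              else sample.int(length(oob))
      Xp <- X
      Xp[, j] <- X[perm, j]
      err1 <- mean(cls[predict_tree_cpp(forest$trees[[t]]$nodes, Xp)] != y_oob)
      acc[j] <- acc[j] + (err1 - err0)
    }
    used <- used + 1L
  }
  if (used == 0L) stop("every tree had an empty OOB set")
  new_importance_result("MDA",
                        stats::setNames(acc / used, forest$vars),
                        used, as.integer(seed))
}

#' Actual impurity reduction (AIR) importance
#'
#' For each variable, the mean over trees of the weighted impurity reduction
#' summed over the nodes split on that variable, minus the same sum for the
#' variable's permuted copy. The copy is drawn once per (tree, variable) as
#' a permutation of the training rows (read through the bootstrap, so bagged
#' duplicates keep a common shadow value, exactly as they keep one response)
#' and competes for splits on equal terms during tree growth. Under a null
#' response the real and permuted columns are exchangeable throughout the
#' recursion, so the score is centred at zero; a target-based encoding
#' fitted before bagging breaks that exchangeability (the real ordering is
#' response-informed, the permuted one is not) and inflates the score.
#'
#' @param forest a `leaky_forest` grown with `air_shadows = TRUE`.
#' @return An `importance_result`.
#' @export
air_importance <- function(forest) {
  if (!isTRUE(forest$params$air_shadows))
    stop("forest was grown without shadow records; refit with air_shadows = TRUE")
  p <- length(forest$vars)
  m <- tree_weighted_sums(forest)
  new_importance_result("AIR",
                        stats::setNames(
                          rowMeans(m[seq_len(p), , drop = FALSE] -
                                     m[p + seq_len(p), , drop = FALSE]),
                          forest$vars),
                        length(forest$trees))
}

# Permutation importance of one fold-trained forest evaluated on the whole
# opposite fold (every tree uses the full fold as its evaluation set).
fold_permutation_importance <- function(forest, eval_data) {
  p <- length(forest$vars)
  truth <- as.character(eval_data[[forest$response]])
  cls <- forest$class_order
  shared_X <- if (!is.null(forest$shared_encodings))
    encode_data(forest$shared_encodings, eval_data, forest$vars)
  acc <- numeric(p)
  m <- nrow(eval_data)
  for (t in seq_along(forest$trees)) {
    X <- if (is.null(forest$trees[[t]]$encodings)) shared_X
         else encode_data(forest$trees[[t]]$encodings, eval_data, forest$vars)
    err0 <- mean(cls[predict_tree_cpp(forest$trees[[t]]$nodes, X)] != truth)
    for (j in seq_len(p)) {
      Xp <- X
      Xp[, j] <- X[sample.int(m), j]
      err1 <- mean(cls[predict_tree_cpp(forest$trees[[t]]$nodes, Xp)] != truth)
      acc[j] <- acc[j] + (err1 - err0)
    }
  }
  acc / length(forest$trees)
}

#' Holdout and independent-holdout permutation importance
#'
#' Rows are split into two random folds. A forest is trained on each fold and
#' its permutation importance computed on the opposite fold (each tree treats
#' the whole opposite fold as its evaluation set); the final score is the
#' mean over the two forests. With `encode_per_fold = FALSE` (Holdout) the
#' level encodings are fitted once on the entire dataset before the fold
#' split, so target-based encodings leak response information across folds.
#' With `encode_per_fold = TRUE` (Independent Holdout — the unbiased variant)
#' each fold's forest fits encodings on its own fold only and the opposite
#' fold is encoded through that map, absent levels handled per policy.
#'
#' @param data data.frame of predictors plus response.
#' @param response name of the response column.
#' @param params a [forest_params()]; `encoding_timing` is ignored (fold
#'   forests always share their fold-level encodings).
#' @param seed integer seed driving the fold split, forest growth and
#'   permutations.
#' @param encode_per_fold logical; `FALSE` = Holdout, `TRUE` = Independent
#'   Holdout.
#' @return An `importance_result` with method `"Holdout"` or
#'   `"IndependentHoldout"`.
#' @export
holdout_importance <- function(data, response, params = forest_params(),
                               seed = 1L, encode_per_fold = FALSE) {
  n <- nrow(data)
  if (n < 4L) stop("need at least 4 rows for two folds")
  y_chr <- as.character(data[[response]])
  class_order <- lex_sort(unique(y_chr))
  vars <- setdiff(names(data), response)

  set.seed(seed)
  idx <- sample.int(n)
  folds <- list(idx[seq_len(floor(n / 2))],
                idx[(floor(n / 2) + 1L):n])
  for (f in folds)
    if (length(unique(y_chr[f])) < 2L)
      stop("a fold contains a single response class; cannot train")

  pooled_enc <- NULL
  if (!encode_per_fold) {
    pooled_enc <- lapply(vars, function(v)
      fit_level_encoding(params$encoding_method, data[[v]], y_chr,
                         class_order = class_order,
                         fit_scope = "full_train",
                         absent_policy = params$absent_policy))
    names(pooled_enc) <- vars
  }

  scores <- matrix(0, nrow = 2L, ncol = length(vars))
  for (f in 1:2) {
    fit_rows <- folds[[f]]
    eval_rows <- folds[[3L - f]]
    fp <- params
    fp$seed <- derive_seed(seed, f)
    fp$air_shadows <- FALSE
    enc <- pooled_enc
    if (encode_per_fold) {
      enc <- lapply(vars, function(v)
        fit_level_encoding(params$encoding_method,
                           data[[v]][fit_rows], y_chr[fit_rows],
                           class_order = class_order,
                           fit_scope = paste0("fold:", f),
                           absent_policy = params$absent_policy))
      names(enc) <- vars
    }
    fr <- fit_forest(data[fit_rows, , drop = FALSE], response, fp,
                     encodings = enc)
    set.seed(derive_seed(seed, f, 7L))
    scores[f, ] <- fold_permutation_importance(
      fr, data[eval_rows, , drop = FALSE])
  }

  new_importance_result(if (encode_per_fold) "IndependentHoldout" else "Holdout",
                        stats::setNames(colMeans(scores), vars),
                        2L * params$n_trees, as.integer(seed))
}
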