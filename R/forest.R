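#' Forest hyperparameters
#'
#' Defaults follow standard classification-forest practice: 500 trees, Gini
#' splitting, `mtry = ceiling(sqrt(p))` (1 when there is a single predictor),
#' terminal nodes of minimum size 1 and no depth limit, so trees are grown to
#' purity.
#'
#' @param n_trees number of trees (default 500).
#' @param mtry number of candidate variables drawn (without replacement) at
#'   each node; `NULL` means `ceiling(sqrt(p))`, resolved at fit time.
#' @param min_node_size nodes smaller than this are not split (default 1).
#' @param seed integer master seed; each tree derives its own stream from
#'   `(seed, tree index)` so refits are bit-reproducible.
#' @param encoding_method `"integer_alpha"`, `"target_twoclass"` or
#'   `"target_pca"`.
#' @param encoding_timing `"before_bagging"` (one encoding per variable fitted
#'   on the full training set and shared by all trees — the leaky mode for
#'   target-based methods) or `"after_bagging"` (each tree refits its
#'   encodings on its own bootstrap sample, in-bag multiplicities included).
#' @param absent_policy how encodings treat levels unseen at fit time; see
#'   [apply_encoding()].
#' @param air_shadows grow each tree over the real variables plus one
#'   permuted copy of each (drawn per tree as a permutation of the training
#'   rows), with the copies competing for splits on equal terms; required by
#'   [air_importance()]. Off the training set the copies are undefined and
#'   rows reaching such a split are routed like absent levels.
#' @return A list of class `forest_params`.
#' @export
forest_params <- function(n_trees = 500L, mtry = NULL, min_node_size = 1L,
                          seed = 1L,
                          encoding_method = c("integer_alpha",
                                              "target_twoclass", "target_pca"),
                          encoding_timing = c("before_bagging",
                                              "after_bagging"),
                          absent_policy = c("majority_child", "strict"),
                          air_shadows = FALSE) {
  encoding_method <- match.arg(encoding_method)
  encoding_timing <- match.arg(encoding_timing)
  absent_policy <- match.arg(absent_policy)
  stopifnot(n_trees >= 1L, min_node_size >= 1L,
            is.null(mtry) || mtry >= 1L)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed),
                 encoding_method = encoding_method,
                 encoding_timing = encoding_timing,
                 absent_policy = absent_policy,
                 air_shadows = isTRUE(air_shadows)),
            class = "forest_params")
}

# Deterministic 31-bit seed derivation (Lehmer-style fold over the arguments);
# keeps every derived seed in 1..2^31-2 for set.seed().
derive_seed <- function(...) {
  xs <- as.numeric(c(...))
  h <- 0
  for (x in xs) h <- (h * 48271 + (x %% 2147483647) + 1) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

#' Gini impurity of a node
#'
#' `1 - sum_c (n_c / n)^2` for class counts `n_c`.
#'
#' @param class_counts vector of nonnegative class counts, at least one > 0.
#' @return Impurity in `[0, 1)`.
#' @export
#' @examples
#' gini_impurity(c(2, 1, 1)) # 0.625
gini_impurity <- function(class_counts) {
  stopifnot(all(class_counts >= 0))
  n <- sum(class_counts)
  if (n == 0) stop("empty node: all class counts are zero")
  1 - sum((class_counts / n)^2)
}

#' Best Gini split at a node
#'
#' Evaluates every candidate variable at thresholds placed midway between
#' consecutive distinct encoded values and returns the split with the largest
#' impurity decrease (`Gini(parent) - weighted Gini(children)`). Ties break to
#' the lower variable index, then the smaller threshold. Missing sentinels
#' (absent levels) are excluded from threshold enumeration. Returns `NULL`
#' when the node is pure or no candidate has two distinct values.
#'
#' @param x numeric matrix of encoded values (rows = samples at the node).
#' @param y class labels at the node (character or factor).
#' @param candidates column indices to consider (default all).
#' @return A list `(variable_index, threshold, impurity_decrease)` or `NULL`.
#' @export
best_split <- function(x, y, candidates = seq_len(ncol(x))) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (length(candidates) == 0L) stop("candidates must be nonempty")
  res <- best_split_cpp(x, as.integer(y), as.integer(candidates),
                        nlevels(y))
  if (length(res) == 0L) NULL else res
}

#' Fit an encoding-aware random forest
#'
#' Grows `n_trees` bagged CART classification trees with Gini splitting over
#' ordinally encoded categorical predictors. With
#' `encoding_timing = "before_bagging"` one encoding per variable is fitted on
#' the full training set and shared across trees, so a target-based encoding
#' has seen the response values of every row — including rows that later fall
#' out of bag. With `"after_bagging"` each tree first draws its bootstrap
#' sample and then fits its own encodings on the in-bag rows only, so its OOB
#' rows are untouched by the encoding.
#'
#' @param train data.frame; all predictor columns categorical (character),
#'   plus the response column.
#' @param response name of the response column.
#' @param params a [forest_params()] object.
#' @param encodings optional named list of pre-fitted `level_encoding`s (one
#'   per predictor), e.g. fitted on pooled data for holdout-style evaluation;
#'   overrides `encoding_method`/`encoding_timing`.
#' @return An object of class `leaky_forest`.
#' @export
fit_forest <- function(train, response, params = forest_params(),
                       encodings = NULL) {
  stopifnot(is.data.frame(train), response %in% names(train))
  n <- nrow(train)
  if (n < 2L) stop("need at least 2 training rows")
  y_chr <- as.character(train[[response]])
  class_order <- lex_sort(unique(y_chr))
  if (length(class_order) < 2L) stop("single-class training data")
  y_int <- match(y_chr, class_order)
  vars <- setdiff(names(train), response)
  if (length(vars) == 0L) stop("no predictor columns")
  p <- length(vars)
  mtry <- if (is.null(params$mtry)) as.integer(ceiling(sqrt(p)))
          else as.integer(params$mtry)
  if (mtry > p) stop("mtry exceeds number of predictors")

  shared_enc <- NULL
  if (!is.null(encodings)) {
    stopifnot(all(vars %in% names(encodings)))
    shared_enc <- encodings[vars]
  } else if (params$encoding_timing == "before_bagging") {
    shared_enc <- lapply(vars, function(v)
      fit_level_encoding(params$encoding_method, train[[v]], y_chr,
                         class_order = class_order,
                         fit_scope = "full_train",
                         absent_policy = params$absent_policy))
    names(shared_enc) <- vars
  }
  X_full <- if (!is.null(shared_enc)) encode_data(shared_enc, train, vars)

  set.seed(params$seed)
  tree_seeds <- sample.int(2147483646L, params$n_trees)

  trees <- vector("list", params$n_trees)
  for (t in seq_len(params$n_trees)) {
    set.seed(tree_seeds[t])
    in_bag <- sample.int(n, n, replace = TRUE)
    oob <- which(tabulate(in_bag, n) == 0L)

    if (is.null(shared_enc)) {
      enc_t <- lapply(vars, function(v)
        fit_level_encoding(params$encoding_method, train[[v]][in_bag],
                           y_chr[in_bag], class_order = class_order,
                           fit_scope = paste0("bootstrap:", t),
                           absent_policy = params$absent_policy))
      names(enc_t) <- vars
      Xb <- encode_data(enc_t, train[in_bag, , drop = FALSE], vars)
    } else {
      enc_t <- NULL
      Xb <- X_full[in_bag, , drop = FALSE]
    }

    shadow <- NULL
    if (params$air_shadows) {
      # corrected-impurity shadows: per (tree, variable), a permutation of
      # the training rows applied to the encoded column; reading it through
      # the bootstrap keeps one common shadow value on all copies of a
      # bagged row, exactly as they share one response. The permuted
      # columns join the candidate set and compete for splits, so under a
      # null response real and shadow columns are exchangeable throughout
      # tree growth.
      Xsrc <- if (is.null(shared_enc)) encode_data(enc_t, train, vars)
              else X_full
      shadow <- matrix(NA_real_, n, p)
      for (j in seq_len(p)) {
        perm <- sample.int(n)
        shadow[, j] <- Xsrc[perm, j]
      }
      Xgrow <- cbind(Xb, shadow[in_bag, , drop = FALSE])
    } else {
      Xgrow <- Xb
    }

    nodes <- grow_tree_cpp(Xgrow, y_int[in_bag], length(class_order),
                           mtry, params$min_node_size, tree_seeds[t])
    trees[[t]] <- list(nodes = nodes, in_bag = in_bag, oob = oob,
                       encodings = enc_t, shadow = shadow)
  }

  structure(list(trees = trees, params = params, mtry = mtry,
                 class_order = class_order, vars = vars,
                 response = response, train = train, n = n,
                 shared_encodings = shared_enc,
                 tree_seeds = tree_seeds),
            class = "leaky_forest")
}

#' @export
print.leaky_forest <- function(x, ...) {
  cat("<leaky_forest> ", length(x$trees), " trees, ", length(x$vars),
      " predictor(s), ", length(x$class_order), " classes\n",
      "encoding: ", x$params$encoding_method, " / ",
      if (is.null(x$shared_encodings)) "after_bagging" else "shared",
      "\n", sep = "")
  invisible(x)
}

# Encodings a given tree routes prediction data through.
tree_encodings <- function(forest, t) {
  if (!is.null(forest$trees[[t]]$encodings)) forest$trees[[t]]$encodings
  else forest$shared_encodings
}

# Majority vote with ties to the first class in class_order.
vote_majority <- function(votes, class_order) {
  pred <- class_order[max.col(votes, ties.method = "first")]
  pred[rowSums(votes) == 0L] <- NA_character_
  pred
}

#' Predict class labels with a fitted forest
#'
#' Each tree routes each row through its own splits using that tree's
#' encodings (absent levels handled per the fitted policy); the forest
#' prediction is the majority vote, ties going to the first class in the
#' forest's class order.
#'
#' @param object a `leaky_forest`.
#' @param newdata data.frame containing the forest's predictor columns.
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @export
predict.leaky_forest <- function(object, newdata, ...) {
  missing_vars <- setdiff(object$vars, names(newdata))
  if (length(missing_vars) > 0L)
    stop("newdata lacks variable(s): ", paste(missing_vars, collapse = ", "))
  n <- nrow(newdata)
  p <- length(object$vars)
  votes <- matrix(0L, nrow = n, ncol = length(object$class_order))
  shared_X <- if (!is.null(object$shared_encodings))
    encode_data(object$shared_encodings, newdata, object$vars)
  # shadow columns are undefined off the training set: missing sentinels
  # route those splits to the larger child
  na_block <- if (object$params$air_shadows) matrix(NA_real_, n, p)
  for (t in seq_along(object$trees)) {
    X <- if (is.null(object$trees[[t]]$encodings)) shared_X
         else encode_data(object$trees[[t]]$encodings, newdata, object$vars)
    if (!is.null(na_block)) X <- cbind(X, na_block)
    pr <- predict_tree_cpp(object$trees[[t]]$nodes, X)
    idx <- cbind(seq_len(n), pr)
    votes[idx] <- votes[idx] + 1L
  }
  vote_majority(votes, object$class_order)
}

#' Out-of-bag predictions
#'
#' For each training row, the majority vote over only the trees for which the
#' row was out of bag. Rows that were in-bag for every tree get `NA` (and are
#' excluded from [oob_error()]).
#'
#' @param forest a `leaky_forest`.
#' @return Character vector of length `nrow(train)`; `NA` where no tree held
#'   the row out of bag.
#' @export
oob_predict <- function(forest) {
  n <- forest$n
  votes <- matrix(0L, nrow = n, ncol = length(forest$class_order))
  shared_X <- if (!is.null(forest$shared_encodings))
    encode_data(forest$shared_encodings, forest$train, forest$vars)
  for (t in seq_along(forest$trees)) {
    oob <- forest$trees[[t]]$oob
    if (length(oob) == 0L) next
    X <- if (is.null(forest$trees[[t]]$encodings))
      shared_X[oob, , drop = FALSE]
    else
      encode_data(forest$trees[[t]]$encodings,
                  forest$train[oob, , drop = FALSE], forest$vars)
    if (forest$params$air_shadows)
      X <- cbind(X, forest$trees[[t]]$shadow[oob, , drop = FALSE])
    pr <- predict_tree_cpp(forest$trees[[t]]$nodes, X)
    idx <- cbind(oob, pr)
    votes[idx] <- votes[idx] + 1L
  }
  vote_majority(votes, forest$class_order)
}
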