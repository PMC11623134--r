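#' Ordinal encodings of categorical predictors
#'
#' A `level_encoding` is a fitted map from the observed levels of one
#' categorical predictor to consecutive integer ranks `1..k`. The map may be
#' target-agnostic (alphabetical integer encoding) or target-based (two-class
#' proportion ordering, or multiclass ordering along the first principal
#' component of the weighted covariance matrix of per-level class
#' probabilities). The fitted object records its provenance (`fit_scope`) so
#' that downstream code can tell whether an encoding saw the full training
#' response (the leaky before-bagging mode) or only one bootstrap sample or
#' cross-validation fold.
#'
#' @param method one of `"integer_alpha"`, `"target_twoclass"`, `"target_pca"`.
#' @param ranks named integer vector, level label -> rank in `1..k`.
#' @param fit_scope provenance string, e.g. `"full_train"`, `"bootstrap:12"`,
#'   `"fold:1"`.
#' @param absent_policy `"majority_child"` (absent levels become a missing
#'   sentinel routed to the larger child at each split) or `"strict"` (error).
#' @param class_order character vector of response classes in the order used
#'   at fit time (empty for target-agnostic encodings).
#'
#' @return An object of class `level_encoding`.
#' @keywords internal
new_level_encoding <- function(method, ranks, fit_scope = "full_train",
                               absent_policy = "majority_child",
                               class_order = character()) {
  stopifnot(method %in% c("integer_alpha", "target_twoclass", "target_pca"),
            absent_policy %in% c("majority_child", "strict"))
  k <- length(ranks)
  if (k == 0L) stop("degenerate predictor: no levels to encode")
  if (!identical(sort(as.integer(ranks)), seq_len(k)))
    stop("ranks must be a bijection onto 1..k")
  structure(
    list(method = method,
         ranks = stats::setNames(as.integer(ranks), names(ranks)),
         fit_scope = fit_scope,
         absent_policy = absent_policy,
         class_order = as.character(class_order)),
    class = "level_encoding")
}

# Locale-independent (C byte order) lexicographic sort used for every
# alphabetical ordering and tie-break in the package.
lex_sort <- function(x) sort(x, method = "radix")

#' @export
print.level_encoding <- function(x, ...) {
  cat("<level_encoding> method=", x$method,
      " k=", length(x$ranks),
      " fit_scope=", x$fit_scope,
      " absent_policy=", x$absent_policy, "\n", sep = "")
  invisible(x)
}

#' Target-agnostic alphabetical integer encoding
#'
#' Assigns ranks by lexicographic (C-locale byte) order of the level labels,
#' so e.g. `"10" < "2"`. The response is never consulted: permuting the class
#' labels cannot change this encoding.
#'
#' @param levels character vector (or factor) of levels; duplicates allowed.
#' @param fit_scope,absent_policy see [new_level_encoding()].
#' @return A `level_encoding` with `method = "integer_alpha"`.
#' @export
#' @examples
#' fit_integer_encoding(c("b", "a", "c"))$ranks
fit_integer_encoding <- function(levels, fit_scope = "full_train",
                                 absent_policy = "majority_child") {
  lv <- unique(as.character(levels))
  lv <- lv[!is.na(lv)]
  if (length(lv) == 0L) stop("degenerate predictor: empty level set")
  lv <- lex_sort(lv)
  new_level_encoding("integer_alpha",
                     stats::setNames(seq_along(lv), lv),
                     fit_scope = fit_scope, absent_policy = absent_policy)
}

#' Target-based encoding for two-class responses
#'
#' Levels are ranked in ascending order of the proportion of observations in
#' the second response class (second element of `class_order`) within each
#' level. Ties are broken lexicographically. For two classes, searching
#' threshold splits on this ordering attains the same optimal Gini split as
#' exhaustively searching all `2^(k-1) - 1` level bipartitions.
#'
#' @param x character vector of levels.
#' @param y response vector with exactly two distinct classes.
#' @param class_order optional class ordering; defaults to the sorted observed
#'   classes.
#' @inheritParams fit_integer_encoding
#' @return A `level_encoding` with `method = "target_twoclass"`.
#' @export
fit_target_encoding_twoclass <- function(x, y, class_order = NULL,
                                         fit_scope = "full_train",
                                         absent_policy = "majority_child") {
  x <- as.character(x); y <- as.character(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.null(class_order)) class_order <- lex_sort(unique(y))
  if (length(class_order) != 2L)
    stop("response has ", length(class_order),
         " classes; use fit_target_encoding_multiclass for > 2 classes")
  lv <- lex_sort(unique(x))
  second <- class_order[2L]
  prop <- vapply(lv, function(l) mean(y[x == l] == second), numeric(1))
  ord <- order(prop, seq_along(lv)) # lv already lexicographic -> tie-break
  new_level_encoding("target_twoclass",
                     stats::setNames(seq_along(lv), lv[ord]),
                     fit_scope = fit_scope, absent_policy = absent_policy,
                     class_order = class_order)
}

#' Target-based encoding for multiclass responses
#'
#' Computes, for each level `l`, the vector `p_l` of class proportions among
#' observations with that level and its weight `w_l = n_l / n`. Levels are
#' then ranked in ascending order of their projection onto the leading
#' eigenvector of the weighted covariance matrix
#' `Sigma = sum_l w_l (p_l - p_bar)(p_l - p_bar)'` with
#' `p_bar = sum_l w_l p_l`. The eigenvector sign is fixed so that its first
#' nonzero coordinate (in `class_order`) is positive; exact projection ties,
#' and the degenerate case `Sigma = 0` (all levels share one class profile),
#' fall back to lexicographic order.
#'
#' @param x character vector of levels.
#' @param y response vector with at least two distinct classes.
#' @inheritParams fit_target_encoding_twoclass
#' @return A `level_encoding` with `method = "target_pca"`.
#' @export
fit_target_encoding_multiclass <- function(x, y, class_order = NULL,
                                           fit_scope = "full_train",
                                           absent_policy = "majority_child") {
  x <- as.character(x); y <- as.character(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.null(class_order)) class_order <- lex_sort(unique(y))
  if (length(class_order) < 2L)
    stop("response must have at least 2 classes")
  lv <- lex_sort(unique(x))
  k <- length(lv)
  C <- length(class_order)
  n <- length(x)

  P <- matrix(0, nrow = k, ncol = C, dimnames = list(lv, class_order))
  w <- numeric(k)
  for (i in seq_len(k)) {
    yi <- y[x == lv[i]]
    w[i] <- length(yi) / n
    P[i, ] <- vapply(class_order, function(cl) mean(yi == cl), numeric(1))
  }

  pbar <- colSums(P * w)
  D <- sweep(P, 2, pbar)
  Sigma <- crossprod(D * sqrt(w)) # sum_l w_l d_l d_l'

  tol <- 1e-12
  if (max(abs(Sigma)) < tol) {
    score <- numeric(k) # zero covariance: all ties -> lexicographic fallback
  } else {
    es <- eigen(Sigma, symmetric = TRUE)
    v <- es$vectors[, 1L]
    nz <- which(abs(v) > tol)[1L]
    if (!is.na(nz) && v[nz] < 0) v <- -v
    score <- as.numeric(P %*% v)
  }
  ord <- order(score, seq_along(lv))
  new_level_encoding("target_pca",
                     stats::setNames(seq_along(lv), lv[ord]),
                     fit_scope = fit_scope, absent_policy = absent_policy,
                     class_order = class_order)
}

#' Fit an encoding by method name
#'
#' Dispatcher used by [fit_forest()]: `"integer_alpha"` ignores `y`;
#' `"target_twoclass"` requires a two-class response; `"target_pca"` works for
#' any number of classes (>= 2).
#'
#' @param method encoding method name.
#' @param x character vector of levels.
#' @param y response vector (ignored for target-agnostic methods).
#' @inheritParams fit_target_encoding_twoclass
#' @return A `level_encoding`.
#' @export
fit_level_encoding <- function(method, x, y = NULL, class_order = NULL,
                               fit_scope = "full_train",
                               absent_policy = "majority_child") {
  switch(method,
    integer_alpha = fit_integer_encoding(x, fit_scope, absent_policy),
    target_twoclass = fit_target_encoding_twoclass(
      x, y, class_order, fit_scope, absent_policy),
    target_pca = fit_target_encoding_multiclass(
      x, y, class_order, fit_scope, absent_policy),
    stop("unknown encoding method: ", method))
}

#' Apply a fitted encoding to a vector of levels
#'
#' Known levels map to their integer ranks. Levels absent at fit time are
#' handled per the encoding's `absent_policy`: `"strict"` raises an error
#' naming the first offending level; `"majority_child"` emits `NA_real_`, a
#' missing sentinel that split evaluation and tree routing send to the child
#' with more in-bag samples.
#'
#' @param enc a `level_encoding`.
#' @param x character vector (or factor) of levels.
#' @return Numeric vector of encoded values (`NA_real_` marks absent levels
#'   under the `majority_child` policy).
#' @export
apply_encoding <- function(enc, x) {
  stopifnot(inherits(enc, "level_encoding"))
  x <- as.character(x)
  out <- as.numeric(enc$ranks[x])
  if (anyNA(out) && enc$absent_policy == "strict") {
    bad <- unique(x[is.na(out)])
    stop("absent level ", bad[1L], " under strict policy")
  }
  out
}

#' Serialise / deserialise an encoding as JSON
#'
#' @param enc a `level_encoding`.
#' @return `encoding_to_json()` returns a JSON string; `encoding_from_json()`
#'   returns a `level_encoding`.
#' @export
encoding_to_json <- function(enc) {
  stopifnot(inherits(enc, "level_encoding"))
  jsonlite::toJSON(
    list(method = enc$method,
         ranks = as.list(enc$ranks),
         fit_scope = enc$fit_scope,
         absent_policy = enc$absent_policy,
         class_order = enc$class_order),
    auto_unbox = TRUE)
}

#' @rdname encoding_to_json
#' @param json JSON string produced by [encoding_to_json()].
#' @export
encoding_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  new_level_encoding(o$method,
                     stats::setNames(unlist(o$ranks), names(o$ranks)),
                     fit_scope = o$fit_scope,
                     absent_policy = o$absent_policy,
                     class_order = as.character(o$class_order))
}

# Encode the predictor columns of a data.frame into a numeric matrix using a
# named list of encodings (one per predictor).
encode_data <- function(encodings, data, vars) {
  n <- nrow(data)
  X <- matrix(NA_real_, nrow = n, ncol = length(vars),
              dimnames = list(NULL, vars))
  for (v in vars) X[, v] <- apply_encoding(encodings[[v]], data[[v]])
  X
}
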