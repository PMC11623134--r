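test_that("gini_impurity follows 1 - sum(p^2)", {
  expect_equal(gini_impurity(c(0, 5, 0)), 0)
  expect_equal(gini_impurity(c(1, 1, 1)), 2 / 3)
  expect_equal(gini_impurity(c(2, 1, 1)), 0.625)
  expect_error(gini_impurity(c(0, 0)), "empty node")
})

test_that("best_split finds the optimal threshold and returns NULL when unsplittable", {
  r <- best_split(matrix(c(1, 1, 2, 2), ncol = 1), c("A", "A", "B", "B"))
  expect_equal(r$threshold, 1.5)
  expect_equal(r$impurity_decrease, 0.5)
  expect_equal(r$variable_index, 1L)

  expect_null(best_split(matrix(1:3, ncol = 1), c("A", "A", "A"))) # pure
  expect_null(best_split(matrix(rep(2, 4), ncol = 1),
                         c("A", "B", "A", "B"))) # constant column
})

test_that("best_split agrees with a brute-force enumeration on random nodes", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    p <- sample(1:3, 1)
    X <- matrix(sample(1:5, n * p, replace = TRUE), ncol = p)
    y <- sample(c("A", "B", "C"), n, replace = TRUE)
    got <- best_split(X, y)
    want <- brute_force_best_split(X, y)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$impurity_decrease, want$decrease, tolerance = 1e-12)
    }
  }
})

test_that("forest fitting is deterministic and trees are structurally reproducible", {
  ds <- generate_null_dataset(60, 8, seed = 3)
  train <- ds$data[ds$train_idx, ]
  p <- forest_params(n_trees = 25, seed = 99)
  f1 <- fit_forest(train, "y", p)
  f2 <- fit_forest(train, "y", p)
  for (t in seq_along(f1$trees)) {
    expect_identical(f1$trees[[t]]$nodes, f2$trees[[t]]$nodes)
    expect_identical(f1$trees[[t]]$in_bag, f2$trees[[t]]$in_bag)
  }
  expect_identical(predict(f1, ds$data), predict(f2, ds$data))
  expect_identical(oob_predict(f1), oob_predict(f2))
})

test_that("a perfectly separating variable yields a pure shallow tree and zero errors", {
  d <- make_separable_data(n = 40, seed = 8)
  f <- fit_forest(d, "y", forest_params(n_trees = 30, seed = 2))
  expect_equal(test_error(f, d), 0)
  expect_equal(oob_error(f), 0)
  # every leaf of every tree is pure
  for (tr in f$trees) {
    leaves <- tr$nodes$split_var == 0L
    expect_true(all(tr$nodes$impurity[leaves] == 0))
  }
})

test_that("bootstrap bags have n draws and OOB fractions match (1 - 1/n)^n", {
  n_total <- 125 # -> 100 training rows
  ds <- generate_null_dataset(n_total, 5, seed = 10)
  train <- ds$data[ds$train_idx, ]
  n <- nrow(train)
  f <- fit_forest(train, "y", forest_params(n_trees = 400, seed = 1))
  frac <- vapply(f$trees, function(tr) {
    expect_length(tr$in_bag, n)
    expect_length(intersect(tr$oob, tr$in_bag), 0L)
    length(tr$oob) / n
  }, numeric(1))
  expected <- (1 - 1 / n)^n
  expect_lt(abs(mean(frac) - expected), 0.01) # ~5 Monte-Carlo SEs
})

test_that("trees are invariant to strictly increasing transforms of encoded values", {
  set.seed(21)
  X <- matrix(as.numeric(sample(1:6, 120, replace = TRUE)), ncol = 2)
  y <- sample.int(3, 60, replace = TRUE)
  t1 <- grow_tree_cpp(X, y, 3L, 2L, 1L, 77L)
  X2 <- X; X2[, 1] <- exp(X2[, 1]) # strictly increasing map on variable 1
  t2 <- grow_tree_cpp(X2, y, 3L, 2L, 1L, 77L)
  expect_identical(t1$split_var, t2$split_var)
  expect_identical(t1$n_node, t2$n_node)
  expect_identical(t1$pred, t2$pred)
  expect_equal(t1$decrease, t2$decrease, tolerance = 1e-12)
})

test_that("reversing an encoding leaves predictions and errors unchanged", {
  ds <- generate_null_dataset(50, 6, seed = 14)
  train <- ds$data[ds$train_idx, ]; test <- ds$data[ds$test_idx, ]
  enc <- list(x1 = fit_integer_encoding(train$x1))
  k <- length(enc$x1$ranks)
  rev_enc <- enc
  rev_enc$x1$ranks <- stats::setNames(k + 1L - enc$x1$ranks,
                                      names(enc$x1$ranks))
  p <- forest_params(n_trees = 50, seed = 31)
  f1 <- fit_forest(train, "y", p, encodings = enc)
  f2 <- fit_forest(train, "y", p, encodings = rev_enc)
  expect_identical(predict(f1, test), predict(f2, test))
  expect_identical(oob_predict(f1), oob_predict(f2))
  expect_equal(oob_error(f1), oob_error(f2))
})

test_that("alphabetical encoding gives identical forests before and after bagging", {
  ds <- generate_null_dataset(40, 3, seed = 6) # k small: every bag sees all levels
  train <- ds$data[ds$train_idx, ]
  f_before <- fit_forest(train, "y",
                         forest_params(n_trees = 20, seed = 5,
                                       encoding_timing = "before_bagging"))
  f_after <- fit_forest(train, "y",
                        forest_params(n_trees = 20, seed = 5,
                                      encoding_timing = "after_bagging"))
  for (t in seq_along(f_before$trees))
    expect_identical(f_before$trees[[t]]$nodes, f_after$trees[[t]]$nodes)
  expect_identical(oob_predict(f_before), oob_predict(f_after))
  expect_identical(f_after$trees[[1]]$encodings$x1$fit_scope, "bootstrap:1")
})

test_that("encoding timing fixes the fit scope and sharing of encodings", {
  ds <- generate_null_dataset(40, 10, seed = 9)
  train <- ds$data[ds$train_idx, ]
  fb <- fit_forest(train, "y",
                   forest_params(n_trees = 5, seed = 2,
                                 encoding_method = "target_pca",
                                 encoding_timing = "before_bagging"))
  expect_identical(fb$shared_encodings$x1$fit_scope, "full_train")
  expect_true(all(vapply(fb$trees, function(tr) is.null(tr$encodings),
                         logical(1))))
  fa <- fit_forest(train, "y",
                   forest_params(n_trees = 5, seed = 2,
                                 encoding_method = "target_pca",
                                 encoding_timing = "after_bagging"))
  scopes <- vapply(fa$trees, function(tr) tr$encodings$x1$fit_scope,
                   character(1))
  expect_identical(scopes, paste0("bootstrap:", 1:5))
})

test_that("vote and leaf ties break to the first class; degenerate predictors never split", {
  d <- data.frame(x1 = rep("only", 10),
                  y = rep(c("A", "B"), 5), stringsAsFactors = FALSE)
  f <- fit_forest(d, "y", forest_params(n_trees = 7, seed = 4))
  # k = 1: no tree can split, every tree is a majority-vote stump
  expect_true(all(vapply(f$trees, function(tr)
    all(tr$nodes$split_var == 0L), logical(1))))
  expect_identical(unique(predict(f, d)), "A")
  expect_error(fit_forest(d[d$y == "A", ], "y", forest_params(n_trees = 2)),
               "single-class")
})

test_that("absent levels at prediction follow the policy", {
  d <- make_separable_data(n = 30, seed = 2)
  newd <- data.frame(x1 = "unseen", stringsAsFactors = FALSE)
  f <- fit_forest(d, "y", forest_params(n_trees = 10, seed = 3,
                                        absent_policy = "majority_child"))
  expect_true(predict(f, newd) %in% f$class_order) # routed, no error
  fs <- fit_forest(d, "y", forest_params(n_trees = 10, seed = 3,
                                         absent_policy = "strict"))
  expect_error(predict(fs, newd), "absent level")
  expect_error(predict(f, data.frame(z = "a")), "lacks variable")
})

test_that("single-tree OOB predictions exist exactly for that tree's OOB rows", {
  ds <- generate_null_dataset(30, 4, seed = 12)
  train <- ds$data[ds$train_idx, ]
  f <- fit_forest(train, "y", forest_params(n_trees = 1, seed = 8))
  pred <- oob_predict(f)
  expect_identical(which(!is.na(pred)), f$trees[[1]]$oob)
})
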