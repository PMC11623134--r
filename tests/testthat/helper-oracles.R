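# Independent oracles and fixture builders used across the suite.

gini_from_labels <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

# Brute-force best split: enumerate every (variable, midpoint threshold) pair
# directly in R. Independent of the C++ search path.
brute_force_best_split <- function(X, y) {
  X <- as.matrix(X)
  best <- NULL
  g0 <- gini_from_labels(y)
  if (g0 == 0) return(NULL) # pure node: no split by contract
  n <- nrow(X)
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1)) {
      thr <- (v[i] + v[i + 1]) / 2
      l <- X[, j] <= thr
      dec <- g0 - mean(l) * gini_from_labels(y[l]) -
        mean(!l) * gini_from_labels(y[!l])
      if (is.null(best) || dec > best$decrease + 1e-12)
        best <- list(variable_index = j, threshold = thr, decrease = dec)
    }
  }
  best
}

# Exhaustive two-class bipartition search: best Gini decrease over all
# 2^(k-1) - 1 splits of the level set into two nonempty groups.
exhaustive_bipartition_best <- function(x, y) {
  lv <- sort(unique(x))
  k <- length(lv)
  stopifnot(k >= 2, k <= 12)
  g0 <- gini_from_labels(y)
  best <- -Inf
  for (mask in 1:(2^(k - 1) - 1)) {
    inset <- lv[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    l <- x %in% inset
    if (!any(l) || all(l)) next
    dec <- g0 - mean(l) * gini_from_labels(y[l]) -
      mean(!l) * gini_from_labels(y[!l])
    if (dec > best) best <- dec
  }
  best
}

# Perfectly separable fixture: the level determines the class.
make_separable_data <- function(n = 30, seed = 1) {
  set.seed(seed)
  lv <- c("a", "b", "c")
  x <- sample(lv, n, replace = TRUE)
  data.frame(x1 = x, y = paste0("C", match(x, lv)),
             stringsAsFactors = FALSE)
}

# Per-cell mean/sd/SE extraction from a summarize_experiment() table.
cell_stat <- function(smry, metric, n = NULL, k = NULL, encoding = NULL,
                      timing = NULL) {
  sel <- smry$metric == metric
  if (!is.null(n)) sel <- sel & smry$n == n
  if (!is.null(k)) sel <- sel & smry$k == k
  if (!is.null(encoding)) sel <- sel & smry$encoding == encoding
  if (!is.null(timing)) sel <- sel & smry$timing == timing
  row <- smry[sel, , drop = FALSE]
  stopifnot(nrow(row) == 1L)
  list(mean = row$mean, sd = row$sd, se = row$sd / sqrt(row$n_reps))
}

# Gini conservation residual for one tree: root impurity minus the leaf
# impurity mixture must equal the weighted sum of split decreases.
tree_conservation_residual <- function(tree, n_inbag) {
  nd <- tree$nodes
  leaves <- nd$split_var == 0L
  internal <- !leaves
  lhs <- nd$impurity[1] -
    sum((nd$n_node[leaves] / n_inbag) * nd$impurity[leaves])
  rhs <- sum((nd$n_node[internal] / n_inbag) * nd$decrease[internal])
  lhs - rhs
}
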