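#' Generate a null classification dataset
#'
#' Each of `p` categorical predictors is sampled i.i.d. uniformly (with
#' replacement) from `k` level labels, and the response is sampled i.i.d.
#' uniformly over `n_classes` class labels — predictors and response are
#' independent by construction, so any apparent signal downstream is bias.
#' `ceiling(train_frac * n)` rows are assigned to training by simple random
#' sampling (unstratified), the rest to testing.
#'
#' @param n total number of rows (>= 5).
#' @param k number of levels per predictor (labels `L001`, `L002`, ...).
#' @param p number of predictor columns (`x1`, `x2`, ...).
#' @param n_classes number of response classes (labels `C1`, `C2`, ...).
#' @param train_frac fraction of rows used for training (default 0.8).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return A list with `data` (data.frame with predictors and response `y`),
#'   `train_idx`, and `test_idx`.
#' @export
generate_null_dataset <- function(n, k, p = 1L, n_classes = 3L,
                                  train_frac = 0.8, seed = 1L) {
  stopifnot(n >= 5L, k >= 1L, p >= 1L, train_frac > 0, train_frac < 1)
  if (n_classes < 2L) stop("need at least 2 response classes")
  set.seed(seed)
  levels_pool <- sprintf("L%03d", seq_len(k))
  classes <- sprintf("C%d", seq_len(n_classes))
  df <- as.data.frame(
    lapply(seq_len(p), function(j) sample(levels_pool, n, replace = TRUE)),
    col.names = paste0("x", seq_len(p)), stringsAsFactors = FALSE)
  df$y <- sample(classes, n, replace = TRUE)
  train_idx <- sort(sample.int(n, ceiling(train_frac * n)))
  list(data = df, train_idx = train_idx,
       test_idx = setdiff(seq_len(n), train_idx))
}

#' Configuration for a null-simulation experiment
#'
#' The full-scale defaults mirror the study conditions of the simulation the
#' package investigates: sample sizes `{20, 50, 100, 150, 200, 400}`, level
#' counts `{1, 5, 10, 35, 50, 100, 150, 200}`, one predictor, three balanced
#' classes, an 80/20 train/test split, 99 replicates and 500-tree forests.
#' Reduced profiles (fewer replicates/trees, smaller grids) give the same
#' qualitative bias patterns at a fraction of the cost and are what the test
#' suite uses.
#'
#' @param n_grid sample sizes to sweep.
#' @param k_grid numbers of predictor levels to sweep.
#' @param p number of predictor variables.
#' @param n_classes number of response classes.
#' @param train_frac training fraction.
#' @param replicates replicate datasets per grid cell.
#' @param n_trees trees per forest.
#' @param encodings subset of `c("integer_alpha", "target_pca")`.
#' @param timings subset of `c("before_bagging", "after_bagging")`.
#' @param vims variable-importance measures to compute per replicate; any of
#'   `"MDI"`, `"MDA"`, `"AIR"`, `"Holdout"`, `"IndependentHoldout"` (the two
#'   holdout measures each train two extra forests per replicate).
#' @param seed master seed; cell/replicate/tree seeds derive from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_grid = c(20L, 50L, 100L, 150L, 200L, 400L),
                              k_grid = c(1L, 5L, 10L, 35L, 50L, 100L, 150L,
                                         200L),
                              p = 1L, n_classes = 3L, train_frac = 0.8,
                              replicates = 99L, n_trees = 500L,
                              encodings = c("integer_alpha", "target_pca"),
                              timings = "before_bagging",
                              vims = c("MDI", "MDA", "AIR", "Holdout",
                                       "IndependentHoldout"),
                              seed = 1L) {
  stopifnot(all(n_grid >= 5L), all(k_grid >= 1L), replicates >= 1L,
            train_frac > 0, train_frac < 1,
            all(encodings %in% c("integer_alpha", "target_twoclass",
                                 "target_pca")),
            all(timings %in% c("before_bagging", "after_bagging")),
            all(vims %in% c("MDI", "MDA", "AIR", "Holdout",
                            "IndependentHoldout")))
  structure(list(n_grid = as.integer(n_grid), k_grid = as.integer(k_grid),
                 p = as.integer(p), n_classes = as.integer(n_classes),
                 train_frac = train_frac,
                 replicates = as.integer(replicates),
                 n_trees = as.integer(n_trees),
                 encodings = encodings, timings = timings, vims = vims,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Metrics for one replicate of one experimental cell.
run_replicate <- function(n, k, p, config, encoding, timing, rep_seed) {
  ds <- generate_null_dataset(n, k, p, config$n_classes, config$train_frac,
                              seed = rep_seed)
  train <- ds$data[ds$train_idx, , drop = FALSE]
  test <- ds$data[ds$test_idx, , drop = FALSE]
  params <- forest_params(n_trees = config$n_trees,
                          seed = derive_seed(rep_seed, 2L),
                          encoding_method = encoding,
                          encoding_timing = timing)
  forest <- fit_forest(train, "y", params)

  out <- list(oob_error = oob_error(forest),
              test_error = test_error(forest, test))
  vim_mean <- function(ir) mean(ir$values)
  if ("MDI" %in% config$vims) out$MDI <- vim_mean(mdi_importance(forest))
  if ("MDA" %in% config$vims)
    out$MDA <- vim_mean(mda_importance(forest, seed = derive_seed(rep_seed, 3L)))
  if ("AIR" %in% config$vims) {
    # the corrected-impurity forest carries competing permuted copies, so it
    # is grown separately and the error metrics stay untouched by them
    air_params <- params
    air_params$air_shadows <- TRUE
    out$AIR <- vim_mean(air_importance(fit_forest(train, "y", air_params)))
  }
  if ("Holdout" %in% config$vims)
    out$Holdout <- vim_mean(holdout_importance(
      train, "y", params, seed = derive_seed(rep_seed, 4L),
      encode_per_fold = FALSE))
  if ("IndependentHoldout" %in% config$vims)
    out$IndependentHoldout <- vim_mean(holdout_importance(
      train, "y", params, seed = derive_seed(rep_seed, 5L),
      encode_per_fold = TRUE))
  out
}

#' Run the factorial null-simulation experiment
#'
#' For every cell of `n_grid x k_grid x encodings x timings` and every
#' replicate: generate a fresh null dataset, fit the forest, and record the
#' OOB error, the independent-test error, and the configured
#' variable-importance measures (each VIM is averaged over variables when
#' `p > 1`). Replicate seeds derive deterministically from
#' `(seed, cell, replicate)`, so any single replicate can be reproduced in
#' isolation. Cells with `k = 1` are retained: the lone predictor can never
#' split, trees are majority-vote stumps and every VIM is exactly zero.
#'
#' @param config a [simulation_config()].
#' @param progress print one line per cell.
#' @return A list of class `simulation_result` with `replicates` (long
#'   data.frame of per-replicate metrics) and `config`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  rows <- list()
  cell_id <- 0L
  for (encoding in config$encodings) for (timing in config$timings)
    for (n in config$n_grid) for (k in config$k_grid) {
      cell_id <- cell_id + 1L
      if (progress)
        message(sprintf("cell %d: n=%d k=%d %s/%s", cell_id, n, k,
                        encoding, timing))
      for (r in seq_len(config$replicates)) {
        rep_seed <- derive_seed(config$seed, cell_id, r)
        metrics <- run_replicate(n, k, config$p, config, encoding, timing,
                                 rep_seed)
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, k = k, p = config$p, encoding = encoding, timing = timing,
          replicate = r, seed = rep_seed,
          metric = names(metrics), value = unlist(metrics),
          row.names = NULL, stringsAsFactors = FALSE)
      }
    }
  structure(list(replicates = do.call(rbind, rows), config = config),
            class = "simulation_result")
}

#' Summarise an experiment into per-cell means and SDs
#'
#' @param result a `simulation_result` from [run_experiment()].
#' @return Long-format data.frame with one row per
#'   `(n, k, p, encoding, timing, metric)` cell: mean, sd and replicate
#'   count.
#' @export
summarize_experiment <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  reps <- result$replicates
  if (is.null(reps) || nrow(reps) == 0L) stop("empty results")
  agg <- stats::aggregate(
    value ~ n + k + p + encoding + timing + metric, data = reps,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n_reps = length(v)))
  out <- cbind(agg[, c("n", "k", "p", "encoding", "timing", "metric")],
               as.data.frame(agg$value))
  out$sd[is.na(out$sd)] <- 0
  out[order(out$encoding, out$timing, out$n, out$k, out$metric), ,
      drop = FALSE]
}
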