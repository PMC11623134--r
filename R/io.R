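#' Read a categorical classification table from CSV
#'
#' All columns are read as character strings — categorical levels are never
#' coerced to numbers, so a level like `"007"` survives verbatim. The class
#' order is the lexicographically sorted set of observed response labels.
#'
#' @param path CSV file with a header row.
#' @param response name of the response column.
#' @return A list with `data` (data.frame of character columns) and
#'   `class_order`.
#' @export
read_table <- function(path, response = "y") {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path)
  if (anyDuplicated(names(df)))
    stop("duplicate column names in ", path)
  if (!response %in% names(df))
    stop("response column '", response, "' not found in ", path)
  list(data = df, class_order = lex_sort(unique(df[[response]])))
}

#' Write experiment or importance results with a reproducibility manifest
#'
#' Importance results become `importance.csv` (variable, method, value,
#' seed); simulation results become `summary.csv` (per-cell means/SDs) and
#' `replicates.csv` (raw per-replicate values). A `manifest.json` capturing
#' the configuration, master seed and package version is always written; it
#' is sufficient to reproduce every output bit-exactly. Existing files are
#' overwritten with a warning.
#'
#' @param results an `importance_result`, a list of them, or a
#'   `simulation_result`.
#' @param outdir output directory (created if needed).
#' @return (Invisibly) the manifest as a list.
#' @export
write_results <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)

  manifest <- list(
    package = "leakyforest",
    version = as.character(utils::packageVersion("leakyforest")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  warn_overwrite <- function(path) {
    if (file.exists(path)) warning("overwriting ", path)
    path
  }

  if (inherits(results, "simulation_result")) {
    utils::write.csv(results$replicates,
                     warn_overwrite(file.path(outdir, "replicates.csv")),
                     row.names = FALSE)
    utils::write.csv(summarize_experiment(results),
                     warn_overwrite(file.path(outdir, "summary.csv")),
                     row.names = FALSE)
    manifest$config <- unclass(results$config)
    manifest$seed <- results$config$seed
  } else {
    if (inherits(results, "importance_result")) results <- list(results)
    stopifnot(all(vapply(results, inherits, logical(1), "importance_result")))
    tab <- do.call(rbind, lapply(results, function(ir)
      data.frame(variable = names(ir$values), method = ir$method,
                 value = unname(ir$values), seed = ir$rng_seed,
                 stringsAsFactors = FALSE)))
    utils::write.csv(tab,
                     warn_overwrite(file.path(outdir, "importance.csv")),
                     row.names = FALSE)
    manifest$methods <- vapply(results, function(ir) ir$method, character(1))
    manifest$seed <- results[[1L]]$rng_seed
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @useDynLib leakyforest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"
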