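#' Run configuration
#'
#' Bundles every tunable of the pipeline: forest hyperparameters, iRF
#' iteration count, cross-validation settings, the correlation-pruning
#' threshold, reduced-model selection, and the network edge filter.
#'
#' @param n_trees,min_leaf,mtry_fraction,bootstrap,max_bins Forest
#'   hyperparameters; see [forest_params()]. Production-scale runs use
#'   1,000 trees with 1,000-patient leaves; the desk-scale defaults keep the
#'   same leaf-occupancy ratio within a factor of two.
#' @param n_iterations iRF iterations (5 matches the production setting).
#' @param test_fraction Held-out sample fraction per cross-validation repeat.
#' @param cv_repeats Number of group-shuffled train/test repeats.
#' @param prune_threshold Absolute Pearson correlation at or above which
#'   features are grouped and pruned (inclusive boundary).
#' @param top_k Number of top-ranked features kept by the reduced model.
#' @param forced_features Features always added to the reduced set (the
#'   access-to-means and restraint proxies).
#' @param loop_edge_fraction Fraction of candidate edges kept by the network
#'   filter (top 1% matches the production analysis).
#' @param loop_n_trees Trees per target model in the all-against-all network
#'   inference (smaller than `n_trees` to keep the loop tractable).
#' @param loop_n_iterations iRF iterations for the per-target network models.
#'   Defaults to 1 (plain weighted-forest importance): iterative reweighting
#'   is a ratchet that concentrates importance mass on arbitrary features of
#'   *unpredictable* targets, flooding the edge filter with spurious
#'   connections, whereas single-pass importance stays near-uniform (weak)
#'   for such targets and concentrated only where real signal exists.
#' @param seed Base seed; all stages derive named substreams from it.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_trees = 50, min_leaf = 250, mtry_fraction = NULL,
                       bootstrap = TRUE, max_bins = 256, n_iterations = 5,
                       test_fraction = 0.2, cv_repeats = 5,
                       prune_threshold = 0.90, top_k = 20,
                       forced_features = c("firearms_per_10k",
                                           "alcohol_per_10k"),
                       loop_edge_fraction = 0.01, loop_n_trees = 20,
                       loop_n_iterations = 1, seed = 1L) {
  assert_scalar_num(test_fraction, "test_fraction", lower = 1e-9,
                    upper = 1 - 1e-9)
  assert_scalar_num(cv_repeats, "cv_repeats", lower = 1, integer = TRUE)
  assert_scalar_num(prune_threshold, "prune_threshold", lower = 1e-9, upper = 1)
  assert_scalar_num(top_k, "top_k", lower = 1, integer = TRUE)
  assert_scalar_num(loop_edge_fraction, "loop_edge_fraction", lower = 1e-12,
                    upper = 1)
  assert_scalar_num(n_iterations, "n_iterations", lower = 1, integer = TRUE)
  assert_scalar_num(loop_n_trees, "loop_n_trees", lower = 1, integer = TRUE)
  assert_scalar_num(loop_n_iterations, "loop_n_iterations", lower = 1,
                    integer = TRUE)
  params <- forest_params(n_trees = n_trees, min_leaf = min_leaf,
                          mtry_fraction = mtry_fraction,
                          bootstrap = bootstrap, seed = seed,
                          max_bins = max_bins)
  structure(
    list(n_trees = params$n_trees, min_leaf = params$min_leaf,
         mtry_fraction = params$mtry_fraction, bootstrap = params$bootstrap,
         max_bins = params$max_bins,
         n_iterations = as.integer(n_iterations),
         test_fraction = test_fraction,
         cv_repeats = as.integer(cv_repeats),
         prune_threshold = prune_threshold, top_k = as.integer(top_k),
         forced_features = as.character(forced_features),
         loop_edge_fraction = loop_edge_fraction,
         loop_n_trees = as.integer(loop_n_trees),
         loop_n_iterations = as.integer(loop_n_iterations),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %d trees x %d iterations, min_leaf=%d, CV %dx%.0f/%.0f, prune >= %.2f, top %d + {%s}, loop top %.1f%%\n",
    x$n_trees, x$n_iterations, x$min_leaf, x$cv_repeats,
    100 * (1 - x$test_fraction), 100 * x$test_fraction, x$prune_threshold,
    x$top_k, paste(x$forced_features, collapse = ", "),
    100 * x$loop_edge_fraction))
  invisible(x)
}

config_forest_params <- function(config, seed = config$seed) {
  forest_params(n_trees = config$n_trees, min_leaf = config$min_leaf,
                mtry_fraction = config$mtry_fraction,
                bootstrap = config$bootstrap, seed = seed,
                max_bins = config$max_bins)
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error so
#' that typos never silently fall back to defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s) in ", path, ": ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}

#' Read a ZIP-level feature table
#'
#' Headered TSV or CSV (by extension) with `zip_id` as the first column and
#' numeric feature columns. Missing values, non-numeric feature cells, and
#' duplicated ZIP identifiers are rejected, never imputed.
#'
#' @param path File path (`.tsv`/`.txt` tab-delimited, `.csv` comma).
#' @return Tibble with `zip_id` (character) plus numeric feature columns, in
#'   file order.
#' @export
read_feature_table <- function(path) {
  x <- read_delim_auto(path)
  if (names(x)[1] != "zip_id") {
    abort(paste0("First column of ", path, " must be 'zip_id'."))
  }
  x$zip_id <- as.character(x$zip_id)
  dup <- unique(x$zip_id[duplicated(x$zip_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicated zip_id in ", path, ": ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  check_numeric_complete(x, path)
  x
}

#' Read a patient table
#'
#' Expects columns `patient_id`, `zip_id`, `age`, `label` with `label` in
#' \{0, 1\} and `age >= 18`.
#'
#' @inheritParams read_feature_table
#' @return Tibble with typed columns.
#' @export
read_patient_table <- function(path) {
  x <- read_delim_auto(path)
  need <- c("patient_id", "zip_id", "age", "label")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0(path, " lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyNA(x[need])) abort(paste0("Missing values in ", path, "."))
  if (!all(x$label %in% c(0, 1))) {
    abort("`label` must be 0 (control) or 1 (case).")
  }
  if (any(x$age < 18)) abort("Ages below 18 are outside the cohort contract.")
  x$patient_id <- as.character(x$patient_id)
  x$zip_id <- as.character(x$zip_id)
  x$age <- as.integer(x$age)
  x$label <- as.integer(x$label)
  x
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

check_numeric_complete <- function(x, path) {
  for (col in setdiff(names(x), "zip_id")) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      abort(paste0("Non-numeric feature column '", col, "' in ", path, "."))
    }
    if (anyNA(v)) {
      abort(paste0("Missing value in ", path, ", column '", col,
                   "', row ", which(is.na(v))[1], "."))
    }
  }
  invisible(x)
}

#' Write a table as headered TSV
#'
#' UTF-8, tab-delimited, '.' decimal; values are written with shortest
#' round-trippable precision so a write/read cycle is lossless.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write a feature-association network
#'
#' Three-column headered TSV (`source`, `target`, `weight`), sorted by
#' descending weight with ties broken lexicographically by source then
#' target so identical networks always produce identical files.
#'
#' @param net A `loop_network` (see [loop_infer()]) or a data frame of
#'   edges with columns `source`, `target`, `weight`.
#' @param path Output TSV path.
#' @param graphml Optional path to additionally write GraphML (via igraph)
#'   for network viewers.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml = NULL) {
  edges <- if (inherits(net, "loop_network")) net$edges else
    tibble::as_tibble(net)
  need <- c("source", "target", "weight")
  if (!all(need %in% names(edges))) {
    abort("Edges need columns source, target, weight.")
  }
  if (any(is.na(edges$weight) | is.nan(edges$weight))) {
    abort("Edge weights contain NaN/NA.")
  }
  edges <- dplyr::arrange(edges[need], dplyr::desc(.data$weight),
                          .data$source, .data$target)
  readr::write_tsv(edges, path, progress = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge list written by [write_network()]
#'
#' @param path TSV path.
#' @return Tibble with `source`, `target`, `weight`.
#' @export
read_network <- function(path) {
  x <- read_delim_auto(path)
  need <- c("source", "target", "weight")
  if (!all(need %in% names(x))) {
    abort(paste0(path, " is not a network file (source/target/weight)."))
  }
  x
}

#' Write planted ground truth as JSON
#'
#' @param truth A `planted_truth` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  jsonlite::write_json(
    list(causal = truth$causal,
         corr_groups = truth$corr_groups,
         intercepts = as.list(truth$intercepts),
         prevalence_by_age = as.list(truth$prevalence_by_age),
         age_cutoff = truth$age_cutoff,
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
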