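#' Forest hyperparameters
#'
#' Bundles the hyperparameters of a single weighted-candidate regression
#' forest. Defaults are desk-scale: 50 trees and a minimum leaf size of 250
#' keep the leaf-size-to-cohort ratio at a 50,000-sample cohort within a
#' factor of two of the production-scale setting of 1,000-patient leaves in
#' a ~400k cohort, while remaining fast on one CPU. For much smaller inputs
#' pass a smaller `min_leaf` explicitly.
#'
#' @param n_trees Number of trees (>= 1).
#' @param min_leaf Minimum number of samples in a leaf (>= 1).
#' @param mtry_fraction Fraction of features drawn (without replacement,
#'   with probability proportional to the feature weights) as split
#'   candidates at each node. `NULL` (default) means `sqrt(F)/F`.
#' @param bootstrap Fit each tree on a bootstrap resample of the rows?
#' @param seed Integer seed; every tree gets its own deterministic substream.
#' @param max_bins Maximum number of split-search bins per feature. Features
#'   with at most `max_bins` distinct values are searched exactly at the
#'   midpoints between consecutive distinct values; denser features are
#'   quantised to quantile bins.
#'
#' @return An object of class `forest_params`.
#' @export
forest_params <- function(n_trees = 50, min_leaf = 250, mtry_fraction = NULL,
                          bootstrap = TRUE, seed = 1L, max_bins = 256) {
  assert_scalar_num(n_trees, "n_trees", lower = 1, integer = TRUE)
  assert_scalar_num(min_leaf, "min_leaf", lower = 1, integer = TRUE)
  if (!is.null(mtry_fraction)) {
    assert_scalar_num(mtry_fraction, "mtry_fraction", lower = 1e-12, upper = 1)
  }
  assert_scalar_num(seed, "seed", integer = TRUE)
  assert_scalar_num(max_bins, "max_bins", lower = 2, upper = 4096,
                    integer = TRUE)
  structure(
    list(n_trees = as.integer(n_trees), min_leaf = as.integer(min_leaf),
         mtry_fraction = mtry_fraction, bootstrap = isTRUE(bootstrap),
         seed = as.integer(seed), max_bins = as.integer(max_bins)),
    class = "forest_params"
  )
}

#' @export
print.forest_params <- function(x, ...) {
  cat(sprintf(
    "<forest_params> trees=%d, min_leaf=%d, mtry_fraction=%s, bootstrap=%s, seed=%d\n",
    x$n_trees, x$min_leaf,
    if (is.null(x$mtry_fraction)) "sqrt(F)/F" else format(x$mtry_fraction),
    x$bootstrap, x$seed))
  invisible(x)
}

resolve_mtry <- function(params, n_features) {
  frac <- params$mtry_fraction %||% (sqrt(n_features) / n_features)
  max(1L, as.integer(ceiling(frac * n_features)))
}

validate_xyw <- function(X, y, feature_weights, row_map = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L) abort("`X` must have at least one row.")
  if (anyNA(X) || anyNA(y)) abort("Missing values are not supported.")
  if (is.null(row_map)) {
    row_map <- seq_len(nrow(X))
    if (length(y) != nrow(X)) abort("`y` must have one value per row of `X`.")
  } else {
    row_map <- as.integer(row_map)
    if (length(y) != length(row_map)) {
      abort("`y` must have one value per entry of `row_map`.")
    }
    if (anyNA(row_map) || any(row_map < 1L) || any(row_map > nrow(X))) {
      abort("`row_map` entries must index rows of `X`.")
    }
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(feature_weights)) {
    feature_weights <- rep(1 / ncol(X), ncol(X))
  }
  if (length(feature_weights) != ncol(X)) {
    abort("`feature_weights` must have one entry per feature.")
  }
  if (any(feature_weights < 0)) abort("Feature weights must be nonnegative.")
  s <- sum(feature_weights)
  if (s <= 0) abort("All feature weights are zero; nothing can be sampled.")
  if (abs(s - 1) > 1e-6) abort("Feature weights must sum to 1.")
  list(X = X, y = as.numeric(y), w = as.numeric(feature_weights),
       row_map = row_map)
}

#' Fit a weighted-candidate regression forest
#'
#' CART-style variance-reduction trees. At each node a candidate set of
#' `ceiling(mtry_fraction * F)` features is drawn without replacement with
#' probability proportional to `feature_weights`; the split maximising the
#' SSE decrease is taken, with ties broken by lower feature index then lower
#' threshold. Leaves predict the mean of their outcomes, so with 0/1 labels
#' every prediction is an estimated case proportion.
#'
#' @param X Numeric matrix (samples x features) or data frame.
#' @param y Numeric outcome; for case/control work a 0/1 vector.
#' @param feature_weights Nonnegative weights summing to 1; `NULL` for
#'   uniform.
#' @param params A [forest_params()] object.
#' @param row_map Optional integer vector mapping each sample to a row of
#'   `X`. When many samples share one feature vector (patients in the same
#'   ZIP code), pass the distinct rows as `X`, per-sample outcomes as `y`,
#'   and their row indices here: the fit is numerically identical to
#'   expanding the rows, at much lower cost. `NULL` means one sample per row.
#'
#' @return An object of class `zf_forest` with elements `trees` (flat node
#'   matrices), `splits` (one audit row per internal node: feature,
#'   threshold, child sizes, child outcome means, child feature means, SSE
#'   decrease), `features`, and `params`.
#' @export
fit_forest <- function(X, y, feature_weights = NULL, params = forest_params(),
                       row_map = NULL) {
  v <- validate_xyw(X, y, feature_weights, row_map)
  mtry <- resolve_mtry(params, ncol(v$X))
  tree_seeds <- with_seed(
    params$seed,
    sample.int(.Machine$integer.max - 1L, params$n_trees, replace = TRUE)
  )
  fit <- cpp_fit_forest(v$X, v$y, v$row_map - 1L, v$w, params$n_trees,
                        params$min_leaf, mtry, params$bootstrap, tree_seeds,
                        params$max_bins)
  structure(
    list(trees = fit$trees, splits = fit$splits,
         raw_importance = as.numeric(fit$raw_importance),
         features = colnames(v$X), params = params, n = length(v$y)),
    class = "zf_forest"
  )
}

#' Fit a single regression tree
#'
#' One unbootstrapped tree from [fit_forest()]; mainly useful for inspecting
#' the recursive partition and for oracle tests against an exhaustive split
#' searcher.
#'
#' @inheritParams fit_forest
#' @return A `zf_forest` with a single tree.
#' @export
fit_tree <- function(X, y, feature_weights = NULL, params = forest_params(),
                     row_map = NULL) {
  params$n_trees <- 1L
  params$bootstrap <- FALSE
  fit_forest(X, y, feature_weights, params, row_map = row_map)
}

#' @export
print.zf_forest <- function(x, ...) {
  cat(sprintf("<zf_forest> %d tree(s), %d features, %d split(s), n=%d\n",
              length(x$trees), length(x$features), nrow(x$splits), x$n))
  invisible(x)
}

#' Split records of a fitted forest
#'
#' @param forest A `zf_forest`.
#' @return A tibble with one row per internal node across all trees:
#'   feature name, threshold, node/child sample counts, child mean outcome,
#'   child mean feature value, and the SSE decrease of the split.
#' @export
split_records <- function(forest) {
  stopifnot(inherits(forest, "zf_forest"))
  s <- tibble::as_tibble(as.data.frame(forest$splits))
  s$feature <- forest$features[s$feature]
  s
}

#' Normalized split-based feature importance
#'
#' Per-feature total SSE decrease across every split of every tree,
#' normalized to sum to one. A forest with no splits anywhere (e.g. a
#' constant outcome) yields the zero vector, flagged via the
#' `"no_splits"` attribute.
#'
#' @param forest A `zf_forest`.
#' @return Named numeric vector over the forest's features, summing to 1
#'   (or all zeros with `attr(, "no_splits") = TRUE`).
#' @export
forest_importance <- function(forest) {
  stopifnot(inherits(forest, "zf_forest"))
  raw <- forest$raw_importance
  names(raw) <- forest$features
  total <- sum(raw)
  if (total <= 0) {
    out <- raw * 0
    attr(out, "no_splits") <- TRUE
    return(out)
  }
  out <- raw / total
  attr(out, "no_splits") <- FALSE
  out
}

#' Predict from a fitted forest
#'
#' The forest prediction is the mean of the per-tree leaf means, so for 0/1
#' outcomes it always lies in `[0, 1]`.
#'
#' @param object A `zf_forest`.
#' @param newdata Matrix or data frame containing at least the model's
#'   feature columns.
#' @param ... Unused.
#' @return Numeric score per row.
#' @export
predict.zf_forest <- function(object, newdata, ...) {
  X <- align_feature_matrix(newdata, object$features)
  as.numeric(cpp_predict_forest(object$trees, X))
}

align_feature_matrix <- function(newdata, features) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(features, names(newdata))
    if (length(missing) > 0) {
      abort(paste0("Missing feature column(s): ",
                   paste(missing, collapse = ", ")))
    }
    X <- as.matrix(newdata[features])
  } else {
    X <- as.matrix(newdata)
    if (!is.null(colnames(X))) {
      missing <- setdiff(features, colnames(X))
      if (length(missing) > 0) {
        abort(paste0("Missing feature column(s): ",
                     paste(missing, collapse = ", ")))
      }
      X <- X[, features, drop = FALSE]
    } else if (ncol(X) != length(features)) {
      abort("`newdata` has the wrong number of columns.")
    }
  }
  storage.mode(X) <- "double"
  if (anyNA(X)) abort("Missing values are not supported.")
  X
}
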