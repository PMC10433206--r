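#' Fit an iterative Random Forest (iRF)
#'
#' Trains a sequence of weighted-candidate regression forests. Iteration 1
#' uses uniform feature weights `1/F`; iteration `t + 1` samples split
#' candidates with probability proportional to iteration `t`'s normalized
#' importance plus a smoothing floor `eps = 1/(100 * F)`, so no feature is
#' ever irrecoverably dropped. Across iterations the candidate mass
#' concentrates on predictive features, which is what makes the final
#' importance ranking of this explainable-AI method sharper than a single
#' forest's.
#'
#' @inheritParams fit_forest
#' @param n_iterations Number of reweighting iterations (>= 1; 5 matches the
#'   production configuration).
#' @param params A [forest_params()] object; each iteration gets its own
#'   deterministic seed substream derived from `params$seed`.
#' @param keep_forests `"all"` retains every iteration's forest (needed if
#'   you want to inspect early iterations), `"last"` keeps only the final
#'   forest (prediction, directionality and ranking only use the final one).
#'
#' @return An object of class `irf_model`: per-iteration weight and
#'   importance vectors (each nonnegative, summing to 1), the forests, the
#'   final importance ranking, and the feature names.
#' @export
fit_irf <- function(X, y, params = forest_params(), n_iterations = 5,
                    keep_forests = c("all", "last"), row_map = NULL) {
  assert_scalar_num(n_iterations, "n_iterations", lower = 1, integer = TRUE)
  keep_forests <- match.arg(keep_forests)
  v <- validate_xyw(X, y, NULL, row_map)
  F_ <- ncol(v$X)
  eps <- 1 / (100 * F_)
  mtry <- resolve_mtry(params, F_)

  # per-iteration, per-tree seed substreams
  tree_seeds <- vapply(seq_len(n_iterations), function(it) {
    with_seed(substream_seed(params$seed, "irf_iteration", it),
              sample.int(.Machine$integer.max - 1L, params$n_trees,
                         replace = TRUE))
  }, integer(params$n_trees))
  tree_seeds <- matrix(tree_seeds, nrow = params$n_trees)

  fit <- cpp_fit_irf(v$X, v$y, v$row_map - 1L, params$n_trees,
                     params$min_leaf, mtry, params$bootstrap, tree_seeds,
                     params$max_bins, as.integer(n_iterations), eps)

  as_forest <- function(it_fit) {
    structure(
      list(trees = it_fit$trees, splits = it_fit$splits,
           raw_importance = as.numeric(it_fit$raw_importance),
           features = colnames(v$X), params = params, n = length(v$y)),
      class = "zf_forest"
    )
  }
  weight_hist <- purrr::map(fit$weights, function(w) {
    names(w) <- colnames(v$X)
    w
  })
  forests <- purrr::map(fit$iterations, as_forest)
  importance_hist <- purrr::map(forests, forest_importance)
  forest <- forests[[n_iterations]]
  if (keep_forests == "last") forests <- list(forest)

  final_imp <- importance_hist[[n_iterations]]
  ord <- order(-as.numeric(final_imp), names(final_imp))
  ranking <- tibble::tibble(
    feature = names(final_imp)[ord],
    importance = as.numeric(final_imp)[ord],
    rank = seq_along(ord)
  )

  structure(
    list(weights = weight_hist, importances = importance_hist,
         forests = forests, final_forest = forest, ranking = ranking,
         features = colnames(v$X), n_iterations = as.integer(n_iterations),
         params = params, keep_forests = keep_forests, n = length(v$y)),
    class = "irf_model"
  )
}

#' @export
print.irf_model <- function(x, ...) {
  cat(sprintf("<irf_model> %d iterations x %d trees, %d features, n=%d\n",
              x$n_iterations, x$params$n_trees, length(x$features), x$n))
  top <- head(x$ranking, 5)
  cat("Top features:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %2d. %-35s %.4f\n", top$rank[i], top$feature[i],
                top$importance[i]))
  }
  invisible(x)
}

#' Predict case scores from an iRF model
#'
#' Scores are the final-iteration forest's mean leaf predictions: with 0/1
#' training labels they are estimated case proportions in `[0, 1]`.
#'
#' @param object An `irf_model`.
#' @param newdata Matrix or data frame with the model's feature columns.
#' @param ... Unused.
#' @return Numeric score per row.
#' @export
predict.irf_model <- function(object, newdata, ...) {
  predict(object$final_forest, newdata)
}

#' Final feature importance of an iRF model
#'
#' @param model An `irf_model`.
#' @param iteration Which iteration's importance to return (default final).
#' @return Named numeric vector summing to 1 (or flagged zero vector).
#' @export
irf_importance <- function(model, iteration = model$n_iterations) {
  stopifnot(inherits(model, "irf_model"))
  assert_scalar_num(iteration, "iteration", lower = 1,
                    upper = model$n_iterations, integer = TRUE)
  model$importances[[iteration]]
}

#' @export
tidy.irf_model <- function(x, ...) {
  per_iter <- purrr::map_dfr(seq_len(x$n_iterations), function(it) {
    tibble::tibble(
      feature = names(x$importances[[it]]),
      iteration = it,
      weight = as.numeric(x$weights[[it]]),
      importance = as.numeric(x$importances[[it]])
    )
  })
  dplyr::left_join(per_iter, x$ranking[c("feature", "rank")], by = "feature")
}

#' @export
glance.irf_model <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_features = length(x$features),
    n_iterations = x$n_iterations,
    n_trees = x$params$n_trees,
    min_leaf = x$params$min_leaf,
    n_splits_final = nrow(x$final_forest$splits),
    top_feature = x$ranking$feature[1],
    top_importance = x$ranking$importance[1]
  )
}
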