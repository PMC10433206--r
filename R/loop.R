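#' All-against-all iRF network inference (iRF-LOOP)
#'
#' For every feature of the (pruned) ZIP table in turn, an iRF is fitted to
#' predict that feature from all remaining features, over ZIP rows as
#' samples. The target model's final normalized importance vector becomes
#' directed edges predictor -> target, so an arrow shows which feature
#' predicts which, and each fitted target's incoming weights sum to one
#' before filtering. Constant target columns cannot be modelled and are
#' skipped with a warning.
#'
#' @param zips ZIP feature table, typically `prune_correlated()$pruned`.
#' @param config A [run_config()]; per-target models use `loop_n_trees`
#'   trees and `loop_n_iterations` iRF iterations (default 1; see
#'   [run_config()] for why network edges use single-pass importance) with
#'   the config's other forest settings and deterministic per-target seed
#'   substreams. `min_leaf` is capped at a tenth of the row count so small
#'   tables can still grow trees.
#' @return An object of class `loop_network`: `edges` (tibble `source`,
#'   `target`, `weight`), `nodes`, `n_candidate_edges` (= F * (F - 1)),
#'   `skipped` (constant targets).
#' @export
loop_infer <- function(zips, config = run_config()) {
  feats <- feature_columns(zips)
  if (length(feats) < 3) abort("Need at least 3 features for iRF-LOOP.")
  X <- as_feature_matrix(zips, feats)
  min_leaf <- min(config$min_leaf, max(1L, nrow(X) %/% 10L))
  skipped <- character()
  edge_list <- list()
  for (j in seq_along(feats)) {
    target <- feats[j]
    yt <- X[, j]
    if (var(yt) == 0) {
      warn(paste0("Skipping constant LOOP target: ", target))
      skipped <- c(skipped, target)
      next
    }
    params <- forest_params(
      n_trees = config$loop_n_trees, min_leaf = min_leaf,
      mtry_fraction = config$mtry_fraction, bootstrap = config$bootstrap,
      seed = substream_seed(config$seed, "loop_target", j),
      max_bins = config$max_bins
    )
    model <- fit_irf(X[, -j, drop = FALSE], yt, params = params,
                     n_iterations = config$loop_n_iterations,
                     keep_forests = "last")
    imp <- irf_importance(model)
    nz <- imp > 0
    if (any(nz)) {
      edge_list[[target]] <- tibble::tibble(
        source = names(imp)[nz], target = target,
        weight = as.numeric(imp[nz])
      )
    }
  }
  edges <- dplyr::bind_rows(edge_list)
  if (nrow(edges) > 0) {
    edges <- dplyr::arrange(edges, dplyr::desc(.data$weight), .data$source,
                            .data$target)
  } else {
    edges <- tibble::tibble(source = character(), target = character(),
                            weight = numeric())
  }
  structure(
    list(edges = edges, nodes = feats,
         n_candidate_edges = length(feats) * (length(feats) - 1L),
         skipped = skipped, edge_fraction = 1),
    class = "loop_network"
  )
}

#' @export
print.loop_network <- function(x, ...) {
  cat(sprintf(
    "<loop_network> %d node(s), %d edge(s) of %d candidate pairs%s\n",
    length(x$nodes), nrow(x$edges), x$n_candidate_edges,
    if (length(x$skipped) > 0)
      paste0(" (skipped: ", paste(x$skipped, collapse = ", "), ")") else ""))
  invisible(x)
}

#' @export
tidy.loop_network <- function(x, ...) {
  x$edges
}

#' Keep the strongest fraction of network edges
#'
#' Retains the `floor(fraction * candidate-edge-count)` highest-weight edges
#' (weight ties broken lexicographically by source then target, so filtering
#' is reproducible), and restricts the node set to the retained endpoints.
#' The candidate count is the number of ordered feature pairs of the
#' original inference, so filtering an already-filtered network at a larger
#' fraction is the identity.
#'
#' @param net A `loop_network`.
#' @param fraction Fraction of candidate edges to keep, in (0, 1].
#' @return A filtered `loop_network`.
#' @export
filter_top_edges <- function(net, fraction = 0.01) {
  stopifnot(inherits(net, "loop_network"))
  assert_scalar_num(fraction, "fraction", lower = 1e-12, upper = 1)
  n_keep <- floor(fraction * net$n_candidate_edges)
  edges <- dplyr::arrange(net$edges, dplyr::desc(.data$weight),
                          .data$source, .data$target)
  edges <- head(edges, n_keep)
  net$edges <- edges
  net$nodes <- sort(unique(c(edges$source, edges$target)))
  net$edge_fraction <- fraction
  net
}

#' First-neighbor subnetwork of one feature
#'
#' The subnetwork induced by a focal node and every node connected to it by
#' an incoming or outgoing edge: edges incident to the focal node plus the
#' edges among its neighbors are kept.
#'
#' @param net A `loop_network`.
#' @param node Focal feature name.
#' @return A `loop_network` restricted to the neighborhood.
#' @export
first_neighbors <- function(net, node) {
  stopifnot(inherits(net, "loop_network"))
  if (!node %in% net$nodes) {
    abort(paste0("Node not in network: ", node))
  }
  e <- net$edges
  nbrs <- unique(c(e$target[e$source == node], e$source[e$target == node]))
  keep_nodes <- union(node, nbrs)
  net$edges <- dplyr::filter(e, .data$source %in% keep_nodes &
                                .data$target %in% keep_nodes)
  net$nodes <- keep_nodes
  net
}
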