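# Exhaustive SSE-minimizing split searcher, independent of the C++ grower:
# scans every feature and every midpoint between adjacent distinct sorted
# values. Used to verify fit_tree node-by-node on small instances.

bf_best_split <- function(X, y, min_leaf) {
  n <- length(y)
  sy <- sum(y)
  syy <- sum(y^2)
  if (n < 2 * min_leaf) return(NULL)
  if ((syy - sy^2 / n) <= 1e-12 * (abs(syy) + 1)) return(NULL)
  best <- NULL
  for (f in seq_len(ncol(X))) {
    u <- sort(unique(X[, f]))
    if (length(u) < 2) next
    cuts <- u[-length(u)] + diff(u) / 2
    for (thr in cuts) {
      left <- X[, f] <= thr
      nl <- sum(left)
      nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      syl <- sum(y[left])
      gain <- syl^2 / nl + (sy - syl)^2 / nr - sy^2 / n
      if (gain <= 0) next
      if (is.null(best) || gain > best$gain ||
          (gain == best$gain &&
           (f < best$feature ||
            (f == best$feature && thr < best$threshold)))) {
        best <- list(feature = f, threshold = thr, gain = gain, left = left)
      }
    }
  }
  best
}

# Walk a fitted single tree and check that every internal node's chosen
# split attains the brute-force optimal SSE decrease (recomputed here with
# independent arithmetic), is admissible (both children >= min_leaf), and
# that every leaf is a node the oracle also refuses to split. When the
# optimum is unique the feature and partition must coincide exactly; when
# several splits tie at the optimal gain, any of them is a correct answer
# (the implementations may order bitwise-tied floating-point gains
# differently), so optimality of the achieved gain is what is asserted.
expect_tree_matches_oracle <- function(fit, X, y, min_leaf) {
  tm <- fit$trees[[1]]
  splits <- fit$splits
  rec <- function(node_id, idx) {
    feat <- tm[node_id, "feature"]
    oracle <- bf_best_split(X[idx, , drop = FALSE], y[idx], min_leaf)
    if (feat == 0) {
      expect_null(oracle)
      expect_equal(unname(tm[node_id, "pred"]), mean(y[idx]), tolerance = 1e-12)
      return(invisible())
    }
    expect_false(is.null(oracle))
    thr <- tm[node_id, "threshold"]
    left_idx <- idx[X[idx, feat] <= thr]
    expect_gte(length(left_idx), min_leaf)
    expect_gte(length(idx) - length(left_idx), min_leaf)
    # gain of the chosen split, recomputed independently; floating-point
    # tolerance is absolute on the node's outcome scale, because gains of
    # nearly pure nodes sit at rounding-noise magnitude
    yl <- y[left_idx]
    yr <- y[setdiff(idx, left_idx)]
    gain_chosen <- sum(yl)^2 / length(yl) + sum(yr)^2 / length(yr) -
      sum(y[idx])^2 / length(idx)
    tol <- 1e-9 * max(1, sum(y[idx]^2))
    expect_lt(abs(gain_chosen - oracle$gain), tol)
    srow <- which(splits[, "node"] == node_id)
    expect_lt(abs(unname(splits[srow, "sse_decrease"]) - oracle$gain), tol)
    rec(tm[node_id, "left"], left_idx)
    rec(tm[node_id, "right"], setdiff(idx, left_idx))
  }
  rec(1, seq_along(y))
}

# small random regression/classification instance
random_instance <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(5:50, 1)
    F_ <- sample(1:4, 1)
    X <- matrix(runif(n * F_), n, F_,
                dimnames = list(NULL, paste0("x", seq_len(F_))))
    y <- if (runif(1) < 0.5) {
      as.numeric(runif(n) < plogis(2 * X[, 1] - 1))
    } else {
      X[, 1] + rnorm(n, sd = 0.3)
    }
    list(X = X, y = y, min_leaf = sample(c(1L, 2L, 5L), 1))
  })
}

# tiny deterministic cohort used across module tests
tiny_cohort <- function(seed = 42, n_zips = 250, n_demo = 30,
                        n_patients = 6000) {
  simulate_cohort(synth_config(
    n_zips = n_zips, n_demo_features = n_demo, n_patients = n_patients,
    corr_groups = list(list(size = 2, r = 0.95)), seed = seed))
}
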