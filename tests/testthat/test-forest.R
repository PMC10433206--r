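test_that("a perfectly separable single feature splits at the midpoint gap", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "f1"))
  y <- c(0, 0, 1, 1)
  tr <- fit_tree(X, y, params = forest_params(min_leaf = 1,
                                              mtry_fraction = 1, seed = 1))
  s <- split_records(tr)
  expect_equal(nrow(s), 1)
  expect_gt(s$threshold, 2)
  expect_lt(s$threshold, 3)
  expect_equal(s$y_mean_left, 0)
  expect_equal(s$y_mean_right, 1)
  expect_equal(predict(tr, X), c(0, 0, 1, 1))
})

test_that("degenerate trees are single leaves with mean predictions", {
  X <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  p <- forest_params(min_leaf = 1, mtry_fraction = 1, seed = 2)

  # pure node: constant outcome
  t0 <- fit_tree(X, rep(0, 10), params = p)
  expect_equal(nrow(t0$splits), 0)
  expect_equal(predict(t0, X), rep(0, 10))

  # min_leaf larger than n
  y <- c(1, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  t1 <- fit_tree(X, y, params = forest_params(min_leaf = 50,
                                              mtry_fraction = 1, seed = 2))
  expect_equal(nrow(t1$splits), 0)
  expect_equal(predict(t1, X), rep(mean(y), 10))

  # leaf prediction is the mean of the 0/1 labels that reached it
  t2 <- fit_tree(matrix(rep(1, 4), ncol = 1), c(1, 0, 0, 0),
                 params = forest_params(min_leaf = 1, seed = 3))
  expect_equal(unique(predict(t2, matrix(1))), 0.25)
})

test_that("forest predictions are bounded leaf-mean averages and deterministic", {
  set.seed(7)
  X <- matrix(rnorm(600), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, plogis(X[, 1]))
  p <- forest_params(n_trees = 15, min_leaf = 10, seed = 5)
  f1 <- fit_forest(X, y, params = p)
  f2 <- fit_forest(X, y, params = p)
  expect_identical(f1$trees, f2$trees)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_true(all(predict(f1, X) >= 0 & predict(f1, X) <= 1))

  # single unbootstrapped tree: forest prediction equals the tree's
  p1 <- forest_params(n_trees = 1, min_leaf = 10, bootstrap = FALSE, seed = 5)
  fs <- fit_forest(X, y, params = p1)
  ts <- fit_tree(X, y, params = p1)
  expect_identical(predict(fs, X), predict(ts, X))
})

test_that("importance is normalized split mass, zero-flagged when splitless", {
  set.seed(8)
  X <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "x1"))
  y <- as.numeric(X[, 1] > 0)
  f <- fit_forest(X, y, params = forest_params(n_trees = 5, min_leaf = 50,
                                               seed = 1))
  imp <- forest_importance(f)
  expect_equal(unname(imp["x1"]), 1)  # every split uses the only feature
  expect_false(attr(imp, "no_splits"))

  f0 <- fit_forest(X, rep(1, 1000),
                   params = forest_params(n_trees = 3, min_leaf = 50,
                                          seed = 1))
  imp0 <- forest_importance(f0)
  expect_true(attr(imp0, "no_splits"))
  expect_equal(sum(imp0), 0)
})

test_that("a planted signal dominates the importance ranking", {
  set.seed(9)
  n <- 2000
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("x%02d", 1:10)))
  y <- as.numeric(X[, 1] > median(X[, 1]))
  f <- fit_forest(X, y, params = forest_params(n_trees = 20, min_leaf = 50,
                                               seed = 3))
  imp <- forest_importance(f)
  expect_identical(names(which.max(imp)), "x01")
})

test_that("iRF starts uniform, conserves weight mass, and reduces to one forest", {
  set.seed(10)
  X <- matrix(rnorm(500 * 8), 500, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- rbinom(500, 1, plogis(X[, 2]))
  p <- forest_params(n_trees = 10, min_leaf = 25, seed = 17)
  m <- fit_irf(X, y, params = p, n_iterations = 3)
  expect_equal(unname(m$weights[[1]]), rep(1 / 8, 8))
  for (it in 1:3) {
    expect_equal(sum(m$weights[[it]]), 1, tolerance = 1e-9)
    expect_true(all(m$weights[[it]] >= 0))
    expect_equal(sum(m$importances[[it]]), 1, tolerance = 1e-9)
  }
  expect_length(m$forests, 3)

  # a single iteration is exactly one uniform-weight forest
  m1 <- fit_irf(X, y, params = p, n_iterations = 1)
  f1 <- fit_forest(X, y, rep(1 / 8, 8),
                   forest_params(n_trees = 10, min_leaf = 25,
                                 seed = substream_seed(17, "irf_iteration", 1)))
  expect_identical(m1$final_forest$trees, f1$trees)
  expect_identical(irf_importance(m1), forest_importance(f1))
})

test_that("iterative reweighting concentrates mass on a planted signal", {
  gained <- vapply(1:20, function(rep) {
    co <- withr::with_seed(rep, {
      n <- 2000
      X <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, sprintf("x%02d", 1:10)))
      y <- rbinom(n, 1, plogis(-1 + 1.2 * X[, 1]))
      list(X = X, y = y)
    })
    m <- fit_irf(co$X, co$y,
                 params = forest_params(n_trees = 15, min_leaf = 50,
                                        seed = 1000 + rep),
                 n_iterations = 5, keep_forests = "last")
    m$weights[[5]][["x01"]] >= m$weights[[1]][["x01"]]
  }, logical(1))
  expect_gte(mean(gained), 0.9)
})

test_that("collapsed row_map fits are identical to expanded-matrix fits", {
  set.seed(11)
  Xr <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  rmap <- sample.int(30, 400, replace = TRUE)
  y <- rbinom(400, 1, plogis(Xr[rmap, 1]))
  p <- forest_params(n_trees = 1, min_leaf = 5, mtry_fraction = 1,
                     bootstrap = FALSE, seed = 21)
  collapsed <- fit_tree(Xr, y, params = p, row_map = rmap)
  expanded <- fit_tree(Xr[rmap, ], y, params = p)
  expect_equal(collapsed$splits[, "feature"], expanded$splits[, "feature"])
  expect_equal(collapsed$splits[, "threshold"], expanded$splits[, "threshold"])
  expect_equal(collapsed$splits[, "n_node"], expanded$splits[, "n_node"])
  expect_equal(collapsed$splits[, "sse_decrease"],
               expanded$splits[, "sse_decrease"], tolerance = 1e-9)
  expect_equal(predict(collapsed, Xr[rmap, ]), predict(expanded, Xr[rmap, ]))
})

test_that("invalid inputs are rejected with clear messages", {
  X <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(10, 1, 0.5)
  expect_error(fit_forest(X[0, , drop = FALSE], numeric(0)), "at least one row")
  expect_error(fit_forest(X, y, feature_weights = c(0, 0)), "zero")
  expect_error(fit_forest(X, y[1:5]), "one value per row")
  f <- fit_forest(X, y, params = forest_params(n_trees = 2, min_leaf = 2,
                                               seed = 1))
  expect_error(predict(f, data.frame(a = 1)), "b")
})

test_that("fit_tree matches the exhaustive split oracle on random instances", {
  for (seed in 1:12) {
    inst <- random_instance(seed)
    fit <- fit_tree(inst$X, inst$y,
                    params = forest_params(min_leaf = inst$min_leaf,
                                           mtry_fraction = 1, seed = seed))
    expect_tree_matches_oracle(fit, inst$X, inst$y, inst$min_leaf)
  }
})

test_that("importance ranking agrees with an independent forest implementation", {
  skip_if_not_installed("randomForest")
  sim <- withr::with_seed(77, {
    X <- matrix(rnorm(1500 * 8), 1500, 8,
                dimnames = list(NULL, paste0("v", 1:8)))
    list(X = X, y = rbinom(1500, 1, plogis(-1 + 1.5 * X[, 2] - 0.8 * X[, 5])))
  })
  ours <- forest_importance(
    fit_forest(sim$X, sim$y,
               params = forest_params(n_trees = 50, min_leaf = 25, seed = 9)))
  # randomForest warns about regression on a 0/1 response; intended here
  rf <- withr::with_seed(10, suppressWarnings(
    randomForest::randomForest(sim$X, sim$y, ntree = 50, nodesize = 25)))
  theirs <- rf$importance[, "IncNodePurity"]
  expect_identical(names(sort(ours, decreasing = TRUE))[1:2],
                   names(sort(theirs, decreasing = TRUE))[1:2])
  expect_gt(cor(ours, theirs[names(ours)], method = "spearman"), 0.6)
})
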