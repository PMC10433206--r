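loop_fixture <- function(seed, n = 400) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * 4), n, 4)
    tibble::tibble(
      zip_id = sprintf("Z%04d", 1:n),
      A = z[, 1], B = z[, 1] + rnorm(n, sd = 0.2),
      C = z[, 2], D = z[, 3], E = z[, 4])
  })
}

test_that("LOOP emits predictor->target edges with unit incoming mass", {
  net <- loop_infer(loop_fixture(51), run_config(loop_n_trees = 8, seed = 2))
  expect_lte(nrow(net$edges), 5 * 4)
  expect_equal(net$n_candidate_edges, 20)
  expect_false(any(net$edges$source == net$edges$target))
  expect_true(all(net$edges$weight >= 0))
  incoming <- tapply(net$edges$weight, net$edges$target, sum)
  expect_true(all(abs(incoming - 1) < 1e-9))

  # the planted dependency dominates the target's incoming weights
  eb <- dplyr::filter(net$edges, target == "B")
  expect_identical(eb$source[which.max(eb$weight)], "A")
})

test_that("LOOP skips constant targets with a warning and is deterministic", {
  zt <- loop_fixture(52)
  zt$flat <- 1
  rc <- run_config(loop_n_trees = 5, seed = 3)
  expect_warning(net <- loop_infer(zt, rc), "flat")
  expect_true("flat" %in% net$skipped)
  expect_false("flat" %in% net$edges$target)

  net2 <- suppressWarnings(loop_infer(zt, rc))
  expect_identical(net$edges, net2$edges)
  expect_error(loop_infer(zt[, 1:3], rc), "at least 3")
})

test_that("top-edge filtering keeps floor(fraction * candidates), ties stable", {
  fake <- structure(
    list(edges = tibble::tibble(
           source = sprintf("s%03d", 1:200),
           target = sprintf("t%03d", 1:200),
           weight = rep(seq(1, 0.05, length.out = 50), 4)),
         nodes = c(sprintf("s%03d", 1:200), sprintf("t%03d", 1:200)),
         n_candidate_edges = 200L, skipped = character(),
         edge_fraction = 1),
    class = "loop_network")
  f <- filter_top_edges(fake, 0.01)
  expect_equal(nrow(f$edges), 2)  # floor(0.01 * 200)
  expect_true(all(f$edges$weight == 1))
  expect_identical(f$edges$source, c("s001", "s051"))  # lexicographic ties

  idf <- filter_top_edges(fake, 1.0)
  expect_equal(nrow(idf$edges), 200)

  # filtering is monotone: edges kept at f are kept at any larger fraction
  small <- filter_top_edges(fake, 0.05)
  large <- filter_top_edges(fake, 0.25)
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(small$edges) %in% key(large$edges)))

  # production-scale arithmetic: 1,536 features
  paper <- structure(
    list(edges = tibble::tibble(source = character(), target = character(),
                                weight = numeric()),
         nodes = sprintf("f%04d", 1:1536),
         n_candidate_edges = 1536L * 1535L, skipped = character(),
         edge_fraction = 1),
    class = "loop_network")
  expect_equal(paper$n_candidate_edges, 2357760)
  expect_equal(floor(0.01 * paper$n_candidate_edges), 23577)
})

test_that("first neighbors induce the focal subnetwork", {
  star <- structure(
    list(edges = tibble::tibble(
           source = c("hub", "hub", "s3", "x"),
           target = c("s1", "s2", "hub", "y"),
           weight = c(0.9, 0.8, 0.7, 0.6)),
         nodes = c("hub", "s1", "s2", "s3", "x", "y"),
         n_candidate_edges = 30L, skipped = character(),
         edge_fraction = 1),
    class = "loop_network")
  fn <- first_neighbors(star, "hub")
  expect_setequal(fn$nodes, c("hub", "s1", "s2", "s3"))
  expect_equal(nrow(fn$edges), 3)

  iso <- first_neighbors(star, "y")  # y has one incoming edge from x
  expect_setequal(iso$nodes, c("y", "x"))

  lonely <- structure(
    list(edges = star$edges[0, ], nodes = "solo",
         n_candidate_edges = 0L, skipped = character(), edge_fraction = 1),
    class = "loop_network")
  fl <- first_neighbors(lonely, "solo")
  expect_identical(fl$nodes, "solo")
  expect_equal(nrow(fl$edges), 0)

  expect_error(first_neighbors(star, "ghost"), "ghost")
})

test_that("planted dependency chains are recovered in the filtered network", {
  withr::with_seed(53, {
    n <- 500
    chain <- matrix(0, n, 3)
    chain[, 1] <- rnorm(n)
    for (k in 2:3) chain[, k] <- chain[, k - 1] + rnorm(n, sd = 0.3)
    noise <- matrix(rnorm(n * 12), n, 12)
    zt <- tibble::as_tibble(as.data.frame(cbind(chain, noise)))
    names(zt) <- c(paste0("link", 1:3), sprintf("n%02d", 1:12))
    zt <- dplyr::mutate(zt, zip_id = sprintf("Z%04d", 1:n), .before = 1)
  })
  net <- loop_infer(zt, run_config(loop_n_trees = 10, seed = 4))
  filtered <- filter_top_edges(net, 6 / net$n_candidate_edges)
  key <- paste(filtered$edges$source, filtered$edges$target)
  expect_true("link1 link2" %in% key)
  expect_true("link2 link3" %in% key)
  fn <- first_neighbors(filtered, "link2")
  expect_true(all(c("link1", "link3") %in% fn$nodes))
})

test_that("single-pass importance avoids spurious edge concentration", {
  # iterative reweighting on unpredictable targets ratchets importance onto
  # arbitrary features; the network default (1 iteration) must keep edges
  # between mutually independent features rare where 5 iterations do not
  zt <- withr::with_seed(8001, {
    n <- 1000
    chain <- matrix(0, n, 6)
    chain[, 1] <- rnorm(n)
    for (k in 2:6) chain[, k] <- chain[, k - 1] + rnorm(n, sd = 0.3)
    zt <- tibble::as_tibble(
      as.data.frame(cbind(chain, matrix(rnorm(n * 44), n, 44))))
    names(zt) <- c(sprintf("link%d", 1:6), sprintf("noise%02d", 1:44))
    dplyr::mutate(zt, zip_id = sprintf("Z%04d", 1:n), .before = 1)
  })
  junk_at <- function(iters) {
    net <- loop_infer(zt, run_config(seed = 8101, loop_n_iterations = iters))
    filtered <- filter_top_edges(net, 0.01)
    chain_nodes <- sprintf("link%d", 1:6)
    mean(!(filtered$edges$source %in% chain_nodes &
           filtered$edges$target %in% chain_nodes))
  }
  expect_lte(junk_at(1), 0.10)
  expect_gt(junk_at(5), 0.5)
})
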