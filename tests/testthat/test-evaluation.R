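test_that("group splits never leak a group across train and test", {
  groups <- rep(sprintf("g%02d", 1:10), each = 10)
  splits <- group_shuffle_split(groups, 0.2, 5, seed = 31)
  expect_length(splits, 5)
  for (s in splits) {
    expect_length(intersect(unique(groups[s$train]), unique(groups[s$test])), 0)
    expect_equal(sort(c(s$train, s$test)), seq_along(groups))
  }
  # 10 equal groups at 20%: exactly 2 groups (20 samples) in test
  expect_true(all(vapply(splits, function(s) length(s$test), numeric(1)) == 20))
  expect_error(group_shuffle_split(rep("only", 5), 0.2, 1, 1), "single group")
})

test_that("precision-recall curves follow the counting definitions", {
  # perfect ranking ends at (recall 1, precision 1)
  pc <- pr_curve(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(pc$recall[length(pc$recall)], 1)
  expect_true(any(pc$recall == 1 & pc$precision == 1))
  expect_equal(auprc(pc), 1)
  # recall is nondecreasing, precision within [0,1]
  expect_true(all(diff(pc$recall) >= 0))
  expect_true(all(pc$precision >= 0 & pc$precision <= 1))

  # worst ranking of one positive among two: AP = 1 * (1/2)
  expect_equal(auprc(c(1, 0), c(0, 1)), 0.5)

  # all-positive labels: precision 1 everywhere
  pc2 <- pr_curve(c(0.2, 0.9, 0.5), c(1, 1, 1))
  expect_true(all(pc2$precision == 1))

  # tied scores are one block
  pc3 <- pr_curve(c(0.5, 0.5, 0.1), c(1, 0, 0))
  expect_equal(nrow(pc3), 2)
  expect_equal(pc3$precision[1], 0.5)

  # a single positive ranked first scores 1 regardless of n
  scores <- c(10, rnorm(99))
  expect_equal(auprc(scores, c(1, rep(0, 99))), 1)

  expect_error(pr_curve(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("AUPRC is invariant to strictly monotone score transforms", {
  withr::with_seed(32, {
    scores <- runif(500)
    labels <- rbinom(500, 1, 0.1)
  })
  a0 <- auprc(scores, labels)
  expect_equal(auprc(qlogis(scores / 2 + 0.25), labels), a0)
  expect_equal(auprc(scores^3 + 5, labels), a0)
})

test_that("random rankings concentrate at the prevalence baseline", {
  p <- 0.05
  vals <- vapply(1:30, function(i) {
    withr::with_seed(100 + i, auprc(runif(4000), rbinom(4000, 1, p)))
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - p), 4 * se)
})

test_that("cross-validation is deterministic and beats chance on planted signal", {
  co <- tiny_cohort(seed = 33, n_zips = 300, n_demo = 30, n_patients = 12000)
  pr <- prune_correlated(co$zips)
  design <- build_design(co$patients, pr$pruned)
  rc <- run_config(n_trees = 20, min_leaf = 60, cv_repeats = 5, seed = 5)
  cv1 <- cross_validate(design, rc)
  cv2 <- cross_validate(design, rc)
  expect_identical(cv1$auprc, cv2$auprc)
  expect_identical(cv1$baseline, cv2$baseline)
  expect_true(all(cv1$auprc >= 0 & cv1$auprc <= 1))
  expect_equal(cv1$baseline,
               vapply(cv1$curves,
                      function(c) attr(c, "n_pos") / attr(c, "n"),
                      numeric(1)))
  # planted signal: most repeats above their prevalence baseline
  expect_gte(sum(cv1$auprc > cv1$baseline), 4)
})

test_that("permuted labels score at the prevalence baseline", {
  co <- tiny_cohort(seed = 34, n_zips = 200, n_demo = 20, n_patients = 8000)
  design <- build_design(co$patients, co$zips)
  design$y <- withr::with_seed(7, sample(design$y))  # break the ZIP linkage
  rc <- run_config(n_trees = 10, min_leaf = 60, cv_repeats = 5, seed = 6)
  cv <- cross_validate(design, rc)
  # null AUPRC fluctuates around prevalence; generous Monte-Carlo band
  expect_lt(abs(cv$mean_auprc - cv$mean_baseline),
            4 * sd(cv$auprc) + 0.25 * cv$mean_baseline)
})

test_that("reduced model selection unions top-k with forced vendor features", {
  co <- tiny_cohort(seed = 35, n_zips = 250, n_demo = 30, n_patients = 10000)
  pr <- prune_correlated(co$zips)
  design <- build_design(co$patients, pr$pruned)
  rc <- run_config(n_trees = 15, min_leaf = 60, cv_repeats = 2, seed = 7)
  res <- reduced_model(design, rc)
  expect_gte(length(res$features), 20)
  expect_lte(length(res$features), 22)
  expect_true(all(c("firearms_per_10k", "alcohol_per_10k") %in% res$features))
  # vendors already in the top 20 shrink the union below 22
  top20 <- head(res$ranking_model$ranking$feature, 20)
  expect_equal(length(res$features),
               20 + length(setdiff(c("firearms_per_10k", "alcohol_per_10k"),
                                   top20)))

  few <- design_subset(design, design$features[1:10])
  expect_error(reduced_model(few, rc), "top_k")
  no_vendor <- design_subset(
    design, setdiff(design$features, "alcohol_per_10k"))
  expect_error(reduced_model(no_vendor, rc), "alcohol_per_10k")
})
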