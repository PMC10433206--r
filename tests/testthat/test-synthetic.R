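test_that("generated feature table has the contracted block structure", {
  co <- tiny_cohort(seed = 1)
  zips <- co$zips
  feats <- setdiff(names(zips), "zip_id")
  monthly <- grep("^clim_(?!static)", feats, value = TRUE, perl = TRUE)
  static <- grep("^clim_static", feats, value = TRUE)
  expect_length(monthly, 144)  # 12 measurement types x 12 months
  expect_length(static, 30)
  demo <- grep("^demo_", feats, value = TRUE)
  expect_length(demo, 30)
  expect_true(all(c("pop_density", "water_land_ratio",
                    "firearms_per_10k", "alcohol_per_10k") %in% feats))
  expect_false(anyNA(zips))
  expect_equal(anyDuplicated(zips$zip_id), 0)
  for (col in demo) {
    expect_true(all(zips[[col]] >= 0 & zips[[col]] <= 1), label = col)
  }
  expect_true(all(zips$firearms_per_10k >= 0))
  expect_true(all(zips$alcohol_per_10k >= 0))
})

test_that("planted correlated groups reach their target correlation", {
  cfg <- synth_config(n_zips = 2000, n_demo_features = 40, n_patients = 100,
                      corr_groups = list(list(size = 2, r = 0.95)), seed = 3)
  zips <- generate_zip_features(cfg)
  groups <- attr(zips, "planted_corr_groups")
  expect_length(groups, 1)
  r <- cor(zips[[groups[[1]][1]]], zips[[groups[[1]][2]]])
  expect_gte(abs(r), 0.90)

  # all within-group pairwise |r| at n >= 1000, several groups
  co <- simulate_cohort(synth_config(n_zips = 1200, n_demo_features = 40,
                                     n_patients = 100, seed = 4))
  for (g in attr(co$zips, "planted_corr_groups")) {
    C <- abs(cor(as.matrix(co$zips[g])))
    expect_gte(min(C), 0.90)
  }
})

test_that("generation is a pure function of the config seed", {
  cfg <- synth_config(n_zips = 150, n_demo_features = 25, n_patients = 800,
                      seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$zips, b$zips)
  expect_identical(a$patients, b$patients)
  expect_identical(a$truth$intercepts, b$truth$intercepts)
})

test_that("intercept calibration hits the target marginal prevalence", {
  # all coefficients zero: the intercept alone must reproduce p = 0.035
  cfg <- synth_config(
    n_zips = 500, n_demo_features = 20, n_patients = 50000,
    prevalence_by_age = c(younger = 0.035, older = 0.035),
    causal_features = tibble::tibble(feature = "demo_0001", coef = 0,
                                     age_band = "all"),
    seed = 12)
  co <- simulate_cohort(cfg)
  p_hat <- mean(co$patients$label)
  se <- sqrt(0.035 * 0.965 / 50000)
  expect_lt(abs(p_hat - 0.035), 3 * se)
  expect_equal(unname(co$truth$intercepts["younger"]), qlogis(0.035),
               tolerance = 1e-6)
})

test_that("a zero-coefficient feature shows no case-rate gradient", {
  cfg <- synth_config(
    n_zips = 500, n_demo_features = 20, n_patients = 50000,
    prevalence_by_age = c(younger = 0.05, older = 0.05),
    causal_features = tibble::tibble(feature = "demo_0003", coef = 0,
                                     age_band = "all"),
    seed = 13)
  co <- simulate_cohort(cfg)
  v <- co$zips$demo_0003[match(co$patients$zip_id, co$zips$zip_id)]
  tert <- cut(v, quantile(v, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE)
  top <- co$patients$label[tert == levels(tert)[3]]
  bottom <- co$patients$label[tert == levels(tert)[1]]
  diff_hat <- mean(top) - mean(bottom)
  se <- sqrt(mean(top) * (1 - mean(top)) / length(top) +
             mean(bottom) * (1 - mean(bottom)) / length(bottom))
  expect_lt(abs(diff_hat), 3 * se)
})

test_that("case rate increases across quintiles of a risk feature", {
  cfg <- synth_config(n_zips = 800, n_demo_features = 20, n_patients = 60000,
                      prevalence_by_age = c(younger = 0.08, older = 0.03),
                      causal_features = tibble::tibble(
                        feature = "demo_0001", coef = 1, age_band = "all"),
                      seed = 14)
  co <- simulate_cohort(cfg)
  v <- co$zips$demo_0001[match(co$patients$zip_id, co$zips$zip_id)]
  q <- cut(v, quantile(v, seq(0, 1, 0.2)), include.lowest = TRUE)
  rates <- tapply(co$patients$label, q, mean)
  # monotone within sampling error: allow one inversion no larger than 2 se
  se <- sqrt(max(rates) / (length(v) / 5))
  expect_true(all(diff(rates) > -2 * se))
  expect_gt(rates[5], rates[1])
})

test_that("age structure matches the cohort contract", {
  co <- tiny_cohort(seed = 2, n_patients = 20000)
  age <- co$patients$age
  expect_true(all(age >= 18))
  frac_older <- mean(age >= 60)
  expect_gt(frac_older, 0.55)
  expect_lt(frac_older, 0.75)
  # counts decline steeply above the cutoff
  expect_lt(sum(age >= 75), sum(age >= 60 & age < 75))
  expect_lt(mean(age >= 80), mean(age >= 60 & age < 80))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_zips = 1), "n_zips")
  expect_error(synth_config(corr_groups = list(list(size = 3, r = 0.5))),
               "0.90")
  expect_error(synth_config(corr_groups = list(list(size = 1, r = 0.95))),
               "size")
  expect_error(synth_config(prevalence_by_age = c(younger = 0, older = 0.1)),
               "strictly")
  cfg <- synth_config(n_zips = 50, n_demo_features = 20, n_patients = 100,
                      causal_features = tibble::tibble(
                        feature = "not_a_column", coef = 1, age_band = "all"),
                      seed = 1)
  zips <- generate_zip_features(cfg)
  expect_error(generate_patients(zips, cfg), "not_a_column")
})
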