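#' Group-shuffled train/test splits
#'
#' Partitions grouping units (ZIP codes), never samples, so no group
#' contributes to both sides of a split — the guard against geospatial
#' leakage. Each repeat randomly permutes the groups and cuts the
#' permutation where the cumulative sample count comes closest to
#' `test_fraction`, with at least one group on each side.
#'
#' @param groups Vector assigning each sample to a group.
#' @param test_fraction Target fraction of samples in the test side.
#' @param n_repeats Number of independent repeats.
#' @param seed Integer seed.
#' @return List of `n_repeats` lists with integer sample indices `train`
#'   and `test`.
#' @export
group_shuffle_split <- function(groups, test_fraction = 0.2, n_repeats = 5,
                                seed = 1L) {
  assert_scalar_num(test_fraction, "test_fraction", lower = 1e-9,
                    upper = 1 - 1e-9)
  assert_scalar_num(n_repeats, "n_repeats", lower = 1, integer = TRUE)
  if (dplyr::n_distinct(groups) < 2) {
    abort("Cannot group-split a single group.")
  }
  purrr::map(seq_len(n_repeats), function(r) {
    draw_group_split(groups, test_fraction,
                     substream_seed(seed, "group_shuffle", r))
  })
}

draw_group_split <- function(groups, test_fraction, seed) {
  tab <- table(groups)
  gnames <- names(tab)
  sizes <- as.integer(tab)
  perm <- with_seed(seed, sample.int(length(gnames)))
  cum <- cumsum(sizes[perm])
  target <- test_fraction * length(groups)
  k <- which.min(abs(cum - target))
  k <- min(max(k, 1L), length(gnames) - 1L)  # at least one group per side
  test_groups <- gnames[perm[seq_len(k)]]
  is_test <- groups %in% test_groups
  list(train = which(!is_test), test = which(is_test))
}

#' Precision-recall curve
#'
#' Points are computed at every distinct score threshold, descending; tied
#' scores are processed as one block. Precision is TP / (TP + FP) and recall
#' TP / (TP + FN); the curve always ends at recall 1.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels 0/1 labels with at least one positive.
#' @return A tibble of class `pr_curve` with columns `threshold`, `tp`,
#'   `fp`, `precision`, `recall`; attributes `n_pos` and `n`.
#' @export
pr_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  if (anyNA(scores) || anyNA(labels)) abort("Missing scores/labels.")
  if (!all(labels %in% c(0, 1))) abort("`labels` must be 0/1.")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) {
    abort("No positive labels: a precision-recall curve is undefined.")
  }
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  block_last <- which(diff(s) != 0)
  last_idx <- c(block_last, length(s))
  tp <- cumsum(l)[last_idx]
  np <- last_idx
  fp <- np - tp
  out <- tibble::tibble(
    threshold = s[last_idx],
    tp = tp, fp = fp,
    precision = tp / np,
    recall = tp / n_pos
  )
  class(out) <- c("pr_curve", class(out))
  attr(out, "n_pos") <- n_pos
  attr(out, "n") <- length(labels)
  out
}

#' Area under the precision-recall curve
#'
#' Average-precision step summation `sum((recall_k - recall_{k-1}) *
#' precision_k)` — no linear interpolation between points, which is known to
#' be optimistic for PR curves. For a random ranking the expected value
#' equals the positive-class prevalence, which is the "random chance"
#' baseline against which models are judged.
#'
#' @param x A `pr_curve`, or a numeric score vector.
#' @param labels 0/1 labels, required when `x` is a score vector.
#' @return A value in \[0, 1\].
#' @export
auprc <- function(x, labels = NULL) {
  curve <- if (inherits(x, "pr_curve")) x else pr_curve(x, labels)
  sum(diff(c(0, curve$recall)) * curve$precision)
}

#' Group-shuffled cross-validation of an iRF model, scored by AUPRC
#'
#' For each repeat the cohort is split by [group_shuffle_split()] on the
#' patient ZIP codes (default 80/20), an iRF is fitted on the training side,
#' held-out patients are scored, and the area under the precision-recall
#' curve is recorded together with the test-side prevalence (the random
#' baseline). A test fold that happens to contain zero cases is redrawn
#' with a warning (at most 10 redraws, then an error) — possible at desk
#' scale with rare outcomes.
#'
#' @param design A [build_design()] object.
#' @param config A [run_config()].
#' @param features Optional feature subset to train on.
#' @param model_tag Label stored in the result (`"all_features"`,
#'   `"reduced"`, ...).
#' @return An object of class `cv_result`: per-repeat AUPRC values,
#'   baselines, their means, the PR curves, and the tag.
#' @export
cross_validate <- function(design, config = run_config(), features = NULL,
                           model_tag = if (is.null(features)) "all_features"
                                       else "reduced") {
  stopifnot(inherits(design, "risk_design"))
  if (!is.null(features)) design <- design_subset(design, features)
  auprcs <- numeric(config$cv_repeats)
  baselines <- numeric(config$cv_repeats)
  curves <- vector("list", config$cv_repeats)
  for (r in seq_len(config$cv_repeats)) {
    split <- NULL
    for (attempt in 0:10) {
      sseed <- substream_seed(config$seed,
                              paste0("cv_", model_tag, "_", design$stratum),
                              r * 100L + attempt)
      cand <- draw_group_split(design$group, config$test_fraction, sseed)
      if (sum(design$y[cand$test]) > 0 && sum(design$y[cand$train]) > 0) {
        split <- cand
        break
      }
      if (attempt == 10) {
        abort("Test fold without cases after 10 redraws; cohort too sparse.")
      }
      warn(sprintf("Repeat %d: fold without cases; redrawing (attempt %d).",
                   r, attempt + 1))
    }
    model <- fit_irf(
      design$X, design$y[split$train],
      params = config_forest_params(config, seed = sseed),
      n_iterations = config$n_iterations, keep_forests = "last",
      row_map = design$row_map[split$train]
    )
    zip_scores <- predict(model, design$X)
    test_scores <- zip_scores[design$row_map[split$test]]
    test_labels <- design$y[split$test]
    curves[[r]] <- pr_curve(test_scores, test_labels)
    auprcs[r] <- auprc(curves[[r]])
    baselines[r] <- mean(test_labels)
  }
  structure(
    list(auprc = auprcs, mean_auprc = mean(auprcs),
         baseline = baselines, mean_baseline = mean(baselines),
         curves = curves, model_tag = model_tag,
         stratum = design$stratum, n_features = length(design$features),
         config = config),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result: %s%s> mean AUPRC %.4f over %d repeats (baseline %.4f, %d features)\n",
    x$model_tag,
    if (is.na(x$stratum)) "" else paste0(", ", x$stratum),
    x$mean_auprc, length(x$auprc), x$mean_baseline, x$n_features))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(
    model = x$model_tag, stratum = x$stratum,
    repeat_id = seq_along(x$auprc),
    auprc = x$auprc, baseline = x$baseline
  )
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    model = x$model_tag, stratum = x$stratum,
    mean_auprc = x$mean_auprc, sd_auprc = sd(x$auprc),
    mean_baseline = x$mean_baseline, n_repeats = length(x$auprc),
    n_features = x$n_features
  )
}

#' Reduced-model selection: top-k features plus forced covariates
#'
#' Fits an iRF on the full design to obtain the final importance ranking,
#' forms the reduced feature set as the top `config$top_k` features united
#' with the forced features (the vendor rates), and cross-validates both the
#' all-features and the reduced model for comparison. Removing the
#' long tail of uninformative features typically removes noise and improves
#' accuracy. Note the ranking is fitted on the full stratum, not nested
#' inside each CV split, so the reduced model's CV estimate carries a mild
#' optimistic bias; the comparison mirrors how the selection is used in
#' practice.
#'
#' @param design A [build_design()] object containing the forced features.
#' @param config A [run_config()].
#' @return An object of class `reduced_model_result`: `features` (the
#'   reduced set), `ranking_model` (the full-design `irf_model`), `cv_all`
#'   and `cv_reduced` (two [cross_validate()] results).
#' @export
reduced_model <- function(design, config = run_config()) {
  stopifnot(inherits(design, "risk_design"))
  if (length(design$features) < config$top_k) {
    abort(sprintf("Design has %d features; need at least top_k = %d.",
                  length(design$features), config$top_k))
  }
  missing <- setdiff(config$forced_features, design$features)
  if (length(missing) > 0) {
    abort(paste0("Forced feature(s) absent from design: ",
                 paste(missing, collapse = ", ")))
  }
  ranking_model <- fit_irf(
    design$X, design$y,
    params = config_forest_params(
      config, seed = substream_seed(config$seed,
                                    paste0("ranking_", design$stratum))),
    n_iterations = config$n_iterations, keep_forests = "all",
    row_map = design$row_map
  )
  top <- head(ranking_model$ranking$feature, config$top_k)
  reduced <- union(top, config$forced_features)
  cv_all <- cross_validate(design, config, model_tag = "all_features")
  cv_reduced <- cross_validate(design, config, features = reduced,
                               model_tag = "reduced")
  structure(
    list(features = reduced, ranking_model = ranking_model,
         cv_all = cv_all, cv_reduced = cv_reduced,
         stratum = design$stratum),
    class = "reduced_model_result"
  )
}

#' @export
print.reduced_model_result <- function(x, ...) {
  cat(sprintf("<reduced_model_result%s> %d features\n",
              if (is.na(x$stratum)) "" else paste0(": ", x$stratum),
              length(x$features)))
  print(x$cv_all)
  print(x$cv_reduced)
  invisible(x)
}

#' @export
tidy.reduced_model_result <- function(x, ...) {
  dplyr::bind_rows(tidy(x$cv_all), tidy(x$cv_reduced))
}
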