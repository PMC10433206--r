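#' Prune highly correlated features
#'
#' High pairwise correlation dilutes split-based importance across
#' near-duplicate features, so before modelling, features are grouped
#' whenever their absolute Pearson correlation (over ZIP rows) is at or
#' above `threshold` (the boundary is inclusive). Groups are the connected
#' components of the correlation graph; from each group the single
#' highest-variance member is retained (ties broken by lexicographically
#' smallest name), all singleton features are kept, and zero-variance
#' columns — whose correlation is undefined and which no tree can split on —
#' are dropped with a warning.
#'
#' @param zips ZIP feature table (tibble with `zip_id` + numeric features).
#' @param threshold Absolute correlation boundary in (0, 1]; default 0.90.
#' @return An object of class `correlation_pruning`: `pruned` (the reduced
#'   table, original column order), `groups` (tibble: `group`, `feature`,
#'   `representative`), `dropped_zero_variance`, `threshold`.
#' @export
prune_correlated <- function(zips, threshold = 0.90) {
  assert_scalar_num(threshold, "threshold", lower = 1e-9, upper = 1)
  if (nrow(zips) < 2) abort("Need at least 2 rows to estimate correlations.")
  feats <- feature_columns(zips)
  X <- as_feature_matrix(zips, feats)

  v <- apply(X, 2, var)
  zero_var <- names(v)[v == 0]
  if (length(zero_var) > 0) {
    warn(paste0("Dropping zero-variance feature(s): ",
                paste(head(zero_var, 10), collapse = ", "),
                if (length(zero_var) > 10) ", ..." else ""))
  }
  keep <- setdiff(feats, zero_var)
  C <- abs(cor(X[, keep, drop = FALSE]))
  diag(C) <- 0
  adj <- C >= threshold

  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  membership <- comp$membership

  groups <- tibble::tibble(feature = keep, component = membership) |>
    dplyr::group_by(.data$component) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::ungroup()

  if (nrow(groups) > 0) {
    groups <- groups |>
      dplyr::mutate(variance = v[.data$feature]) |>
      dplyr::group_by(.data$component) |>
      dplyr::mutate(representative = .data$feature ==
                      .data$feature[order(-.data$variance, .data$feature)][1]) |>
      dplyr::ungroup()
    group_ids <- dplyr::dense_rank(groups$component)
    groups <- tibble::tibble(group = group_ids, feature = groups$feature,
                             variance = groups$variance,
                             representative = groups$representative) |>
      dplyr::arrange(.data$group, dplyr::desc(.data$representative),
                     .data$feature)
    removed <- groups$feature[!groups$representative]
  } else {
    groups <- tibble::tibble(group = integer(), feature = character(),
                             variance = numeric(), representative = logical())
    removed <- character()
  }

  retained <- setdiff(keep, removed)
  pruned <- zips[c("zip_id", intersect(feats, retained))]
  structure(
    list(pruned = pruned, groups = groups,
         dropped_zero_variance = zero_var, threshold = threshold,
         n_removed = length(removed) + length(zero_var),
         n_retained = length(retained)),
    class = "correlation_pruning"
  )
}

#' @export
print.correlation_pruning <- function(x, ...) {
  cat(sprintf(
    "<correlation_pruning> |r| >= %.2f: %d group(s), %d feature(s) removed, %d retained\n",
    x$threshold, dplyr::n_distinct(x$groups$group), x$n_removed, x$n_retained))
  invisible(x)
}

#' @export
tidy.correlation_pruning <- function(x, ...) {
  x$groups
}

#' Build a patient-level design from a ZIP feature table
#'
#' Attaches each patient's ZIP-level covariates without materialising the
#' expanded matrix: the design keeps the distinct ZIP rows and a
#' patient-to-row map, which downstream forests consume directly.
#'
#' @param patients Patient tibble (`patient_id`, `zip_id`, `age`, `label`).
#' @param zips ZIP feature table (typically after [prune_correlated()]).
#' @param features Feature subset to carry; default all.
#' @param stratum Optional label (e.g. `"older"`).
#' @return An object of class `risk_design`.
#' @export
build_design <- function(patients, zips, features = NULL, stratum = NA_character_) {
  unknown <- setdiff(unique(patients$zip_id), zips$zip_id)
  if (length(unknown) > 0) {
    abort(paste0("Patient ZIP code(s) missing from the feature table: ",
                 paste(head(unknown, 5), collapse = ", "),
                 if (length(unknown) > 5)
                   sprintf(", ... (%d total)", length(unknown)) else ""))
  }
  features <- features %||% feature_columns(zips)
  X <- as_feature_matrix(zips, features)
  row_map <- match(patients$zip_id, zips$zip_id)
  structure(
    list(patient_id = patients$patient_id,
         y = as.integer(patients$label),
         age = patients$age,
         X = X, row_map = row_map,
         group = patients$zip_id,
         features = features,
         stratum = stratum),
    class = "risk_design"
  )
}

#' @export
print.risk_design <- function(x, ...) {
  cat(sprintf(
    "<risk_design%s> %d patients over %d ZIPs, %d features, %d cases (%.2f%%)\n",
    if (is.na(x$stratum)) "" else paste0(": ", x$stratum),
    length(x$y), nrow(x$X), length(x$features), sum(x$y),
    100 * mean(x$y)))
  invisible(x)
}

design_subset <- function(design, features) {
  missing <- setdiff(features, design$features)
  if (length(missing) > 0) {
    abort(paste0("Feature(s) not in design: ", paste(missing, collapse = ", ")))
  }
  design$X <- design$X[, features, drop = FALSE]
  design$features <- features
  design
}

#' Join patients to ZIP features and split the cohort at an age cutoff
#'
#' Patients aged at or above the cutoff form the `older` design, the rest
#' the `younger` design; their sizes always sum to the input size. Each
#' design carries its ZIP's (retained) features and the patient's ZIP as the
#' cross-validation grouping factor.
#'
#' @inheritParams build_design
#' @param age_cutoff Years; the boundary patient (age == cutoff) is `older`.
#' @return List with `older` and `younger` [build_design()] objects.
#' @export
join_and_split <- function(patients, zips, age_cutoff = 60,
                           features = NULL) {
  assert_scalar_num(age_cutoff, "age_cutoff", integer = TRUE)
  is_older <- patients$age >= age_cutoff
  list(
    older = build_design(patients[is_older, ], zips, features, "older"),
    younger = build_design(patients[!is_older, ], zips, features, "younger")
  )
}

#' Cohort counts by age stratum
#'
#' @param patients Patient tibble.
#' @param age_cutoff Years (boundary goes to the older stratum).
#' @return Tibble with one row per stratum plus a `total` row: `n`,
#'   `cases`, `controls`.
#' @export
cohort_summary <- function(patients, age_cutoff = 60) {
  stratum <- ifelse(patients$age >= age_cutoff, "older", "younger")
  per <- tibble::tibble(stratum = stratum, label = patients$label) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n = dplyr::n(), cases = sum(.data$label),
                     controls = sum(.data$label == 0), .groups = "drop")
  dplyr::bind_rows(
    per,
    tibble::tibble(stratum = "total", n = sum(per$n),
                   cases = sum(per$cases), controls = sum(per$controls))
  )
}
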