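#' Run the full geospatial risk pipeline
#'
#' End-to-end orchestration mirroring the study design: (optionally)
#' generate a synthetic cohort, prune correlated features, join patients to
#' ZIP covariates and split the cohort at the age cutoff, then per age
#' stratum fit the full iRF ranking, select and cross-validate the reduced
#' model (top-k + vendor rates) against the all-features model, estimate
#' per-feature directionality, and finally infer the iRF-LOOP feature
#' network with its top-edge filter and the alcohol-vendor first-neighbor
#' subnetwork. All artifacts are written under `out_dir` together with a
#' manifest (config echo and hash, seeds, stage timings, file digests).
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @param synth A [synth_config()] for synthetic runs, or `NULL` when
#'   supplying real tables.
#' @param zips,patients User-supplied tables (ignored when `synth` given).
#' @param age_cutoff Cohort split age; defaults to the synthetic config's
#'   cutoff or 60.
#' @param subnetwork_node Focal feature of the reported first-neighbor
#'   subnetwork.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, config = run_config(),
                         synth = synth_config(), zips = NULL,
                         patients = NULL, age_cutoff = NULL,
                         subnetwork_node = "alcohol_per_10k") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("zipforest")),
    status = "running",
    config = unclass(config),
    config_hash = digest::digest(unclass(config)),
    base_seed = config$seed,
    stages = list()
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  write_manifest()

  stage <- function(name, code) {
    zf_log("stage %s: start", name)
    t0 <- proc.time()[3]
    result <- tryCatch(code, error = function(e) {
      manifest$status <<- paste0("failed at stage: ", name)
      write_manifest()
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 3))
    zf_log("stage %s: done", name)
    result
  }

  if (!is.null(synth)) {
    cohort <- stage("generate", {
      co <- simulate_cohort(synth)
      write_tsv_table(co$zips, file.path(out_dir, "zips.tsv"))
      write_tsv_table(co$patients, file.path(out_dir, "patients.tsv"))
      write_planted_truth(co$truth, file.path(out_dir, "truth.json"))
      co
    })
    zips <- cohort$zips
    patients <- cohort$patients
    age_cutoff <- age_cutoff %||% synth$age_cutoff
  } else {
    if (is.null(zips) || is.null(patients)) {
      abort("Provide either `synth` or both `zips` and `patients`.")
    }
    age_cutoff <- age_cutoff %||% 60
  }

  pruning <- stage("prune", {
    pr <- prune_correlated(zips, config$prune_threshold)
    write_tsv_table(pr$pruned, file.path(out_dir, "pruned.tsv"))
    jsonlite::write_json(
      list(threshold = pr$threshold, groups = pr$groups,
           dropped_zero_variance = pr$dropped_zero_variance,
           n_removed = pr$n_removed, n_retained = pr$n_retained),
      file.path(out_dir, "pruning_groups.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pr
  })

  designs <- stage("join_split", {
    write_tsv_table(cohort_summary(patients, age_cutoff),
                    file.path(out_dir, "cohort_summary.tsv"))
    join_and_split(patients, pruning$pruned, age_cutoff)
  })

  for (st in c("older", "younger")) {
    design <- designs[[st]]
    stage(paste0("model_", st), {
      sdir <- file.path(out_dir, st)
      dir.create(sdir, showWarnings = FALSE)
      rm_res <- reduced_model(design, config)
      write_tsv_table(rm_res$ranking_model$ranking,
                      file.path(sdir, "ranking.tsv"))
      writeLines(rm_res$features, file.path(sdir, "reduced_features.txt"))
      write_tsv_table(tidy(rm_res), file.path(sdir, "cv_auprc.tsv"))
      dirs <- effect_directions(rm_res$ranking_model, rm_res$features)
      write_tsv_table(dirs, file.path(sdir, "directions.tsv"))
      curves <- purrr::imap_dfr(rm_res$cv_reduced$curves, function(cv, i) {
        dplyr::mutate(tibble::as_tibble(cv), repeat_id = i,
                      model = "reduced")
      })
      curves_all <- purrr::imap_dfr(rm_res$cv_all$curves, function(cv, i) {
        dplyr::mutate(tibble::as_tibble(cv), repeat_id = i,
                      model = "all_features")
      })
      write_tsv_table(dplyr::bind_rows(curves_all, curves),
                      file.path(sdir, "pr_curves.tsv"))
      NULL
    })
  }

  stage("loop_network", {
    net <- loop_infer(pruning$pruned, config)
    filtered <- filter_top_edges(net, config$loop_edge_fraction)
    write_network(filtered, file.path(out_dir, "network.tsv"))
    manifest$loop <- list(
      n_candidate_edges = net$n_candidate_edges,
      edge_definition = "ordered feature pairs F*(F-1); filter keeps floor(fraction * candidates)",
      n_edges_kept = nrow(filtered$edges),
      skipped_targets = net$skipped
    )
    if (subnetwork_node %in% filtered$nodes) {
      sub <- first_neighbors(filtered, subnetwork_node)
      write_network(sub, file.path(out_dir, "subnetwork.tsv"))
    } else {
      zf_log("focal node %s not in filtered network; no subnetwork written",
             subnetwork_node)
    }
    NULL
  })

  manifest$status <- "complete"
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  digests <- tools::md5sum(files)
  manifest$outputs <- purrr::map2(
    basename(names(digests)), unname(digests),
    function(f, d) list(file = f, md5 = d))
  names(manifest$outputs) <- sub(paste0("^", out_dir, "/?"), "",
                                 names(digests))
  write_manifest()
  invisible(manifest)
}

#' Summarise a completed pipeline run
#'
#' Reads the artifacts of [run_pipeline()] and assembles the tabular
#' analogue of the study's result figures: per-stratum AUPRC distributions
#' against the prevalence baseline, the top-feature table with risk /
#' protective directions, and network summary statistics. Also writes
#' `report.md` in the run directory; regeneration is idempotent.
#'
#' @param out_dir A completed run directory.
#' @return A list with `cohort`, `cv`, `top_features`, `network_summary`.
#' @export
pipeline_report <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.json")
  needed <- c("manifest.json", "cohort_summary.tsv",
              "older/cv_auprc.tsv", "younger/cv_auprc.tsv",
              "older/directions.tsv", "younger/directions.tsv",
              "network.tsv")
  missing <- needed[!file.exists(file.path(out_dir, needed))]
  if (length(missing) > 0) {
    abort(paste0("Incomplete run; missing artifact(s): ",
                 paste(missing, collapse = ", ")))
  }
  manifest <- jsonlite::read_json(manifest_path)
  if (!identical(manifest$status, "complete")) {
    abort(paste0("Run did not complete (status: ", manifest$status, ")."))
  }

  cohort <- readr::read_tsv(file.path(out_dir, "cohort_summary.tsv"),
                            show_col_types = FALSE)
  cv <- purrr::map_dfr(c("older", "younger"), function(st) {
    readr::read_tsv(file.path(out_dir, st, "cv_auprc.tsv"),
                    show_col_types = FALSE)
  })
  top_features <- purrr::map_dfr(c("older", "younger"), function(st) {
    dplyr::mutate(
      readr::read_tsv(file.path(out_dir, st, "directions.tsv"),
                      show_col_types = FALSE),
      stratum = st)
  })
  net <- read_network(file.path(out_dir, "network.tsv"))
  network_summary <- tibble::tibble(
    n_edges = nrow(net),
    n_nodes = dplyr::n_distinct(c(net$source, net$target)),
    max_weight = if (nrow(net) > 0) max(net$weight) else NA_real_,
    n_candidate_edges = manifest$loop$n_candidate_edges
  )

  lines <- c(
    "# Pipeline report", "",
    "## Cohort", knitr_kable_fallback(cohort),
    "", "## Cross-validated AUPRC (per repeat)", knitr_kable_fallback(
      dplyr::summarise(
        dplyr::group_by(cv, .data$stratum, .data$model),
        mean_auprc = mean(.data$auprc), mean_baseline = mean(.data$baseline),
        n_repeats = dplyr::n(), .groups = "drop")),
    "", "## Top features and directions", knitr_kable_fallback(
      head(dplyr::arrange(top_features, .data$stratum,
                          dplyr::desc(.data$r_squared)), 30)),
    "", "## Network", knitr_kable_fallback(network_summary)
  )
  writeLines(lines, file.path(out_dir, "report.md"))
  list(cohort = cohort, cv = cv, top_features = top_features,
       network_summary = network_summary)
}

# minimal markdown table writer (avoids a knitr dependency)
knitr_kable_fallback <- function(df) {
  df <- as.data.frame(df)
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, format = "g", digits = 6) else as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  c(header, sep, rows)
}
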