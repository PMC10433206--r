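#' Configuration for the synthetic ZIP-level cohort generator
#'
#' The generator emulates the structure of a geospatial case-control study:
#' a ZIP-level feature table (144 monthly climate columns = 12 measurement
#' types x 12 months, 30 static climate columns, a block of demographic
#' proportion columns plus population density and water/land ratio, and
#' firearms/alcohol vendors per 10,000 residents) and a patient table
#' (id, ZIP, age, 0/1 case label). Case labels are drawn from a sparse
#' logistic model on standardized ZIP features with known coefficient signs,
#' so planted risk/protective structure can be recovered and scored.
#'
#' @param n_zips Number of ZIP codes (>= 2).
#' @param n_demo_features Number of demographic proportion columns. The
#'   desk-scale default 200 stands in for a production-scale census block of
#'   ~1,600 columns; set 1606 to reproduce full-scale structural counts.
#' @param n_patients Cohort size.
#' @param prevalence_by_age Named probabilities `c(younger = , older = )`
#'   giving the case prevalence below / at-or-above the age cutoff. Defaults
#'   mirror a cohort where attempts are concentrated under 60 (7.2% vs 1.6%).
#' @param causal_features Tibble/data frame with columns `feature`,
#'   `coef` (signed logistic coefficient on the standardized feature), and
#'   `age_band` (`"all"`, `"younger"`, `"older"`).
#' @param corr_groups List of planted correlated feature groups, each a list
#'   or named vector with `size` (>= 2) and `r` (target pairwise |Pearson
#'   correlation|, >= 0.90 — groups exist to exercise the pruning
#'   threshold). Groups are planted over trailing demographic columns.
#' @param age_cutoff Age (years) separating the two prevalence regimes.
#' @param seed Integer seed; generation is a pure function of the config.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_zips = 2000,
                         n_demo_features = 200,
                         n_patients = 50000,
                         prevalence_by_age = c(younger = 0.072, older = 0.016),
                         causal_features = default_causal_features(),
                         corr_groups = list(list(size = 3, r = 0.95),
                                            list(size = 5, r = 0.92)),
                         age_cutoff = 60,
                         seed = 1L) {
  assert_scalar_num(n_zips, "n_zips", lower = 2, integer = TRUE)
  assert_scalar_num(n_demo_features, "n_demo_features", lower = 1,
                    integer = TRUE)
  assert_scalar_num(n_patients, "n_patients", lower = 1, integer = TRUE)
  assert_scalar_num(age_cutoff, "age_cutoff", lower = 19, upper = 100,
                    integer = TRUE)
  assert_scalar_num(seed, "seed", integer = TRUE)
  if (!all(c("younger", "older") %in% names(prevalence_by_age))) {
    abort("`prevalence_by_age` needs entries named 'younger' and 'older'.")
  }
  if (any(prevalence_by_age <= 0 | prevalence_by_age >= 1)) {
    abort("Prevalence values must lie strictly in (0, 1).")
  }
  causal_features <- tibble::as_tibble(causal_features)
  need <- c("feature", "coef", "age_band")
  if (!all(need %in% names(causal_features))) {
    abort("`causal_features` needs columns feature, coef, age_band.")
  }
  if (!all(causal_features$age_band %in% c("all", "younger", "older"))) {
    abort("`age_band` must be one of 'all', 'younger', 'older'.")
  }
  corr_groups <- purrr::map(corr_groups, function(g) {
    g <- as.list(g)
    if (is.null(g$size) || is.null(g$r)) {
      abort("Each corr group needs `size` and `r`.")
    }
    assert_scalar_num(g$size, "corr group size", lower = 2, integer = TRUE)
    if (g$r < 0.90 || g$r >= 1) {
      abort("Corr group target |r| must be in [0.90, 1): groups exist to exercise the pruning threshold.")
    }
    list(size = as.integer(g$size), r = as.numeric(g$r))
  })
  n_group_cols <- sum(purrr::map_int(corr_groups, "size"))
  if (n_group_cols > n_demo_features / 2) {
    abort("Planted corr groups would occupy more than half the demographic block; increase n_demo_features.")
  }
  structure(
    list(n_zips = as.integer(n_zips),
         n_demo_features = as.integer(n_demo_features),
         n_patients = as.integer(n_patients),
         prevalence_by_age = prevalence_by_age,
         causal_features = causal_features,
         corr_groups = corr_groups,
         age_cutoff = as.integer(age_cutoff),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Default planted causal features
#'
#' Five ZIP-level features with known signs: one protective and one risk
#' demographic proportion, one climate column, and the two vendor-rate
#' columns (both risk), all acting across the whole age range.
#'
#' @return Tibble with columns `feature`, `coef`, `age_band`.
#' @export
default_causal_features <- function() {
  tibble::tibble(
    feature = c("demo_0001", "demo_0002", "clim_prcp_m04",
                "firearms_per_10k", "alcohol_per_10k"),
    coef = c(0.9, -0.9, 0.6, 0.5, 0.5),
    age_band = "all"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d ZIPs, %d demographic cols, %d patients, cutoff %d, seed %d\n",
    x$n_zips, x$n_demo_features, x$n_patients, x$age_cutoff, x$seed))
  cat(sprintf("  prevalence: younger %.3f / older %.3f; %d causal feature(s); %d corr group(s)\n",
              x$prevalence_by_age[["younger"]], x$prevalence_by_age[["older"]],
              nrow(x$causal_features), length(x$corr_groups)))
  invisible(x)
}

climate_measurement_types <- function() {
  c("tmax", "tmin", "tavg", "prcp", "srad", "wind",
    "vapr", "dewp", "rhum", "cloud", "snow", "pet")
}

static_climate_names <- function() {
  c("clim_static_elevation", "clim_static_urban_cover",
    sprintf("clim_static_%02d", 3:30))
}

#' Generate the ZIP-level feature table
#'
#' Produces one row per ZIP with 144 monthly climate columns (12 measurement
#' types x 12 months, sharing a per-type latent so same-type months are
#' moderately correlated), 30 static climate columns, `n_demo_features`
#' demographic proportion columns in (0, 1), population density, water/land
#' area ratio, and two per-10,000 vendor-rate columns drawn from a
#' zero-inflated gamma. Configured correlated groups are planted as
#' noised/sign-flipped copies of a latent seed column (rescaled linearly into
#' \[0, 1\], which preserves Pearson correlation) over the trailing
#' demographic columns, so group membership is exactly known.
#'
#' @param config A [synth_config()].
#' @return A tibble with `zip_id` plus all feature columns; planted group
#'   membership is recorded in the `"planted_corr_groups"` attribute.
#' @export
generate_zip_features <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_zips
  with_seed(substream_seed(config$seed, "zip_features"), {
    zip_id <- sprintf("Z%05d", seq_len(n))

    # monthly climate: per-type latent + independent monthly noise
    types <- climate_measurement_types()
    base <- c(25, 5, 15, 80, 180, 12, 1.2, 8, 65, 50, 10, 95)
    amp <- c(12, 12, 12, 30, 90, 3, 0.6, 6, 10, 15, 12, 40)
    sds <- c(6, 6, 6, 25, 30, 3, 0.4, 4, 8, 12, 8, 20)
    clim <- list()
    for (ti in seq_along(types)) {
      latent <- rnorm(n)
      for (m in 1:12) {
        mu <- base[ti] + amp[ti] * cos(2 * pi * (m - 7) / 12)
        clim[[sprintf("clim_%s_m%02d", types[ti], m)]] <-
          mu + sds[ti] * (0.7 * latent + 0.714 * rnorm(n))
      }
    }

    stat <- list()
    stat[["clim_static_elevation"]] <- exp(rnorm(n, 6, 1))
    stat[["clim_static_urban_cover"]] <- 100 * rbeta(n, 2, 5)
    for (j in 3:30) {
      stat[[sprintf("clim_static_%02d", j)]] <- rnorm(n, 0, 1)
    }

    demo <- list()
    for (j in seq_len(config$n_demo_features)) {
      base_p <- runif(1, 0.02, 0.6)
      demo[[sprintf("demo_%04d", j)]] <- plogis(qlogis(base_p) + 0.8 * rnorm(n))
    }

    # plant correlated groups over the trailing demographic columns
    group_sizes <- purrr::map_int(config$corr_groups, "size")
    group_cols <- list()
    if (length(group_sizes) > 0) {
      col_idx <- config$n_demo_features - sum(group_sizes) + 1L
      for (gi in seq_along(config$corr_groups)) {
        g <- config$corr_groups[[gi]]
        sigma <- sqrt(1 / g$r - 1)
        z <- rnorm(n)
        members <- character(g$size)
        for (k in seq_len(g$size)) {
          v <- (if (k %% 2 == 0) -1 else 1) * (z + sigma * rnorm(n))
          v <- (v - min(v)) / (max(v) - min(v))  # linear: preserves |r|
          nm <- sprintf("demo_%04d", col_idx)
          demo[[nm]] <- v
          members[k] <- nm
          col_idx <- col_idx + 1L
        }
        group_cols[[gi]] <- members
      }
    }

    other <- list(
      pop_density = exp(rnorm(n, 5, 1.2)),
      water_land_ratio = rbeta(n, 0.4, 4),
      firearms_per_10k = ifelse(runif(n) < 0.35, 0,
                                rgamma(n, shape = 1.5, scale = 1.2)),
      alcohol_per_10k = ifelse(runif(n) < 0.25, 0,
                               rgamma(n, shape = 2, scale = 1.5))
    )

    zips <- tibble::as_tibble(c(list(zip_id = zip_id), clim, stat, demo,
                                other))
    attr(zips, "planted_corr_groups") <- group_cols
    zips
  })
}

# Age sampler: counts ramp up towards the cutoff then decay sharply above
# it, mirroring a cohort concentrated around 60 with ~2/3 at or above.
sample_ages <- function(n, age_cutoff) {
  young_ages <- 18:(age_cutoff - 1)
  young_w <- seq(0.25, 1, length.out = length(young_ages))
  old_ages <- age_cutoff:95
  old_w <- exp(-0.07 * (old_ages - age_cutoff))
  band <- runif(n) < 0.34
  ages <- integer(n)
  ages[band] <- sample(young_ages, sum(band), replace = TRUE, prob = young_w)
  ages[!band] <- sample(old_ages, sum(!band), replace = TRUE, prob = old_w)
  ages
}

#' Generate a patient cohort from a ZIP feature table
#'
#' Patients are assigned ZIPs by a nonuniform multinomial (probability
#' proportional to population density), ages from a distribution that ramps
#' up towards the cutoff and decays sharply above it, and case labels from
#' `Bernoulli(plogis(intercept_band + sum(coef * z)))` where `z` are the
#' ZIP's standardized causal feature values and the per-band intercept is
#' calibrated so the realized marginal prevalence matches
#' `config$prevalence_by_age`.
#'
#' @param zips Table from [generate_zip_features()].
#' @param config The same [synth_config()].
#' @return A list with `patients` (tibble: `patient_id`, `zip_id`, `age`,
#'   `label`) and `truth` (a `planted_truth` object recording causal
#'   features, signs, age bands, correlated-group membership, and the
#'   calibrated intercepts).
#' @export
generate_patients <- function(zips, config) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(zips) == 0) abort("`zips` is empty.")
  missing <- setdiff(config$causal_features$feature, names(zips))
  if (length(missing) > 0) {
    abort(paste0("Causal feature(s) absent from the ZIP table: ",
                 paste(missing, collapse = ", ")))
  }
  n <- config$n_patients
  with_seed(substream_seed(config$seed, "patients"), {
    zi <- sample.int(nrow(zips), n, replace = TRUE,
                     prob = zips$pop_density %||% rep(1, nrow(zips)))
    age <- sample_ages(n, config$age_cutoff)
    band <- ifelse(age >= config$age_cutoff, "older", "younger")

    cf <- config$causal_features
    zmat <- scale(as.matrix(zips[cf$feature]))
    zmat[is.nan(zmat)] <- 0  # zero-variance causal column contributes nothing
    lp <- rep(0, n)
    for (k in seq_len(nrow(cf))) {
      act <- if (cf$age_band[k] == "all") rep(TRUE, n) else band == cf$age_band[k]
      lp[act] <- lp[act] + cf$coef[k] * zmat[zi[act], k]
    }

    intercepts <- c(younger = NA_real_, older = NA_real_)
    p <- rep(NA_real_, n)
    for (b in c("younger", "older")) {
      sel <- band == b
      target <- config$prevalence_by_age[[b]]
      bint <- uniroot(function(a) mean(plogis(a + lp[sel])) - target,
                      lower = -30, upper = 10, tol = 1e-10)$root
      intercepts[b] <- bint
      p[sel] <- plogis(bint + lp[sel])
    }
    label <- rbinom(n, 1, p)

    patients <- tibble::tibble(
      patient_id = sprintf("P%07d", seq_len(n)),
      zip_id = zips$zip_id[zi],
      age = as.integer(age),
      label = as.integer(label)
    )
    truth <- structure(
      list(causal = dplyr::mutate(cf, sign = sign(.data$coef)),
           corr_groups = attr(zips, "planted_corr_groups") %||% list(),
           intercepts = intercepts,
           prevalence_by_age = config$prevalence_by_age,
           age_cutoff = config$age_cutoff,
           seed = config$seed),
      class = "planted_truth"
    )
    list(patients = patients, truth = truth)
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("<planted_truth>\n")
  print(x$causal)
  cat(sprintf("  %d correlated group(s); intercepts younger %.2f / older %.2f\n",
              length(x$corr_groups), x$intercepts[["younger"]],
              x$intercepts[["older"]]))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: [generate_zip_features()] then
#' [generate_patients()].
#'
#' @param config A [synth_config()].
#' @return List with `zips`, `patients`, `truth`.
#' @export
simulate_cohort <- function(config = synth_config()) {
  zips <- generate_zip_features(config)
  gp <- generate_patients(zips, config)
  list(zips = zips, patients = gp$patients, truth = gp$truth)
}
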