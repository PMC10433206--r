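#' Per-split effect points for one feature
#'
#' Every split on the feature in the final-iteration forest contributes two
#' points: the left child's (mean feature value, mean outcome, size) and the
#' right child's. With 0/1 labels the outcome means are the children's case
#' proportions, so these points trace how the predicted case rate moves with
#' the feature.
#'
#' @param model An `irf_model`.
#' @param feature Feature name.
#' @return Tibble with columns `x` (child mean feature value), `y` (child
#'   mean outcome), `w` (child sample count).
#' @export
collect_split_effects <- function(model, feature) {
  stopifnot(inherits(model, "irf_model"))
  if (!feature %in% model$features) {
    abort(paste0("Feature not in model: ", feature))
  }
  s <- model$final_forest$splits
  rows <- which(model$features[s[, "feature"]] == feature)
  if (length(rows) == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), w = numeric()))
  }
  tibble::tibble(
    x = c(s[rows, "x_mean_left"], s[rows, "x_mean_right"]),
    y = c(s[rows, "y_mean_left"], s[rows, "y_mean_right"]),
    w = c(s[rows, "n_left"], s[rows, "n_right"])
  )
}

weighted_linear_fit <- function(x, y, w) {
  xb <- weighted.mean(x, w)
  yb <- weighted.mean(y, w)
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0) return(list(slope = NA_real_, r_squared = NA_real_))
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  sst <- sum(w * (y - yb)^2)
  r2 <- if (sst <= 0) 1 else {
    fitted <- yb + slope * (x - xb)
    max(0, min(1, 1 - sum(w * (y - fitted)^2) / sst))
  }
  list(slope = slope, r_squared = r2)
}

#' Risk/protective direction of one feature
#'
#' Fits a size-weighted least-squares line through the per-split child
#' (mean feature value, mean outcome) points of [collect_split_effects()].
#' A positive slope means higher feature values predict cases (`risk`); a
#' negative slope means they predict controls (`protective`). A feature that
#' was never split on, or whose split points share a single x value (slope
#' undefined), is `undetermined`.
#'
#' @inheritParams collect_split_effects
#' @return One-row tibble: `feature`, `slope`, `r_squared`, `direction`,
#'   `n_splits`.
#' @export
effect_direction <- function(model, feature) {
  pts <- collect_split_effects(model, feature)
  n_splits <- nrow(pts) / 2
  if (n_splits == 0) {
    return(tibble::tibble(feature = feature, slope = NA_real_,
                          r_squared = NA_real_, direction = "undetermined",
                          n_splits = 0))
  }
  fit <- weighted_linear_fit(pts$x, pts$y, pts$w)
  if (is.na(fit$slope)) {
    warn(paste0("All split points of '", feature,
                "' share one feature value; slope undefined."))
    direction <- "undetermined"
  } else if (fit$slope > 0) {
    direction <- "risk"
  } else if (fit$slope < 0) {
    direction <- "protective"
  } else {
    direction <- "undetermined"
  }
  tibble::tibble(feature = feature, slope = fit$slope,
                 r_squared = fit$r_squared, direction = direction,
                 n_splits = n_splits)
}

#' Directionality of all (or selected) model features
#'
#' @param model An `irf_model`.
#' @param features Feature names; default all model features, in ranking
#'   order.
#' @return Tibble with one row per feature (see [effect_direction()]).
#' @export
effect_directions <- function(model, features = NULL) {
  stopifnot(inherits(model, "irf_model"))
  features <- features %||% model$ranking$feature
  purrr::map_dfr(features, function(f) effect_direction(model, f))
}
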