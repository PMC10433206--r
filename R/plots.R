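#' @export
autoplot.pr_curve <- function(object, ...) {
  baseline <- attr(object, "n_pos") / attr(object, "n")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh", colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = baseline, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = "Precision-recall curve",
                  subtitle = sprintf("dashed: prevalence baseline %.3f",
                                     baseline)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$auprc)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA,
                          fill = "#a6bddb") +
    ggplot2::geom_jitter(width = 0.05, height = 0) +
    ggplot2::geom_hline(yintercept = object$mean_baseline,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(y = "AUPRC", x = NULL,
                  title = sprintf("Cross-validated AUPRC (%s)",
                                  object$model_tag),
                  subtitle = "dashed: random-chance (prevalence) baseline") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.reduced_model_result <- function(object, ...) {
  d <- tidy(object)
  baseline <- mean(c(object$cv_all$baseline, object$cv_reduced$baseline))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$auprc,
                                  fill = .data$model)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.05, height = 0) +
    ggplot2::geom_hline(yintercept = baseline, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(y = "AUPRC", x = NULL,
                  title = "All features vs reduced model",
                  subtitle = "dashed: random-chance (prevalence) baseline") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.loop_network <- function(object, ...) {
  if (nrow(object$edges) == 0) {
    abort("Cannot plot an empty network.")
  }
  g <- igraph::graph_from_data_frame(object$edges, directed = TRUE)
  set.seed(1)  # layout only; analysis results never depend on this
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(name = igraph::V(g)$name,
                          x = lay[, 1], y = lay[, 2])
  edges <- dplyr::left_join(object$edges,
                            dplyr::rename(nodes, source = "name",
                                          x0 = "x", y0 = "y"),
                            by = "source")
  edges <- dplyr::left_join(edges,
                            dplyr::rename(nodes, target = "name",
                                          x1 = "x", y1 = "y"),
                            by = "target")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$weight),
      colour = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 3, colour = "#2c7fb8") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "iRF-LOOP feature network",
                  subtitle = "arrow: source feature predicts target")
}

#' Plot feature directionality
#'
#' Horizontal bars of the per-feature split-regression slopes, coloured by
#' risk (positive) vs protective (negative) direction.
#'
#' @param directions Output of [effect_directions()].
#' @param top_n Show the `top_n` features by `|slope| * r_squared`.
#' @return A ggplot object.
#' @export
plot_directions <- function(directions, top_n = 20) {
  d <- directions |>
    dplyr::filter(.data$direction != "undetermined") |>
    dplyr::mutate(score = abs(.data$slope) * .data$r_squared) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    head(top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$slope,
    y = stats::reorder(.data$feature, abs(.data$slope)),
    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(risk = "#e6b800",
                                          protective = "#33cccc")) +
    ggplot2::labs(x = "Split-regression slope", y = NULL,
                  title = "Feature directionality",
                  subtitle = "positive slope predicts cases; negative predicts controls") +
    ggplot2::theme_minimal()
}
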