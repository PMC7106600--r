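# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_histogram geom_point
#'   geom_hline geom_vline labs facet_wrap theme_minimal coord_flip
NULL

#' Plot DEQ component loadings
#'
#' @param object A `pvq_pca`.
#' @param ... Unused.
#' @return A ggplot: loadings of each item on the two retained components.
#' @export
autoplot.pvq_pca <- function(object, ...) {
  tidy.pvq_pca(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$item, y = .data$loading)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~component) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      title = "DEQ component loadings",
      subtitle = "PC1: low self-esteem; PC2: interpersonal sensitivity",
      x = NULL, y = "loading"
    ) +
    ggplot2::theme_minimal()
}

#' Plot component scores colored by quadrant
#'
#' @param scores A tibble with `pc1_score`, `pc2_score` (e.g. from
#'   [build_feature_table()]).
#' @param threshold Quadrant threshold (default 0).
#' @return A ggplot scatter with the quadrant boundaries.
#' @export
plot_quadrants <- function(scores, threshold = 0) {
  scores <- dplyr::mutate(
    scores,
    quadrant = assign_quadrant(.data$pc1_score, .data$pc2_score, threshold)
  )
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$pc1_score, y = .data$pc2_score,
                                       color = .data$quadrant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "PC1 (low self-esteem)",
                  y = "PC2 (interpersonal sensitivity)",
                  color = "quadrant") +
    ggplot2::theme_minimal()
}

#' Plot the repeated cross-validation accuracy distribution
#'
#' @param object A `pvq_cv_repeated`.
#' @param ... Unused.
#' @return A ggplot histogram of per-repeat accuracy with the mean marked.
#' @export
autoplot.pvq_cv_repeated <- function(object, ...) {
  ggplot2::ggplot(object$per_repeat, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::geom_vline(xintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::labs(
      title = sprintf("Repeated %d-fold cross-validation (%d repeats)",
                      object$k, object$repeats),
      x = "pooled accuracy per repeat", y = "repeats"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a patient's factor attribution
#'
#' @param object A `pvq_profile`.
#' @param ... Unused.
#' @return A ggplot bar chart of signed factor strengths.
#' @export
autoplot.pvq_profile <- function(object, ...) {
  f <- object$factor_findings
  if (nrow(f) == 0) {
    rlang::abort("profile has no factor findings to plot",
                 class = "pvq_plot_error")
  }
  ggplot2::ggplot(f, ggplot2::aes(
    x = stats::reorder(paste0(.data$variable, "=", .data$state),
                       .data$strength),
    y = .data$strength, fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      title = sprintf("Patient %s: risk %.1f%%", object$patient_id,
                      100 * object$risk_probability),
      x = NULL, y = "leave-one-variable-out log risk ratio"
    ) +
    ggplot2::theme_minimal()
}
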