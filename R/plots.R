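# Figure-style plots: diversity by group, diversity by extinction class,
# predictor scatter panels, viability change panels.

#' Boxplot of relative diversity by inbreeding level
#'
#' @param diversity Tibble from [estimate_diversity()].
#' @param lines Manifest with `line_id` and `group`.
#' @return A ggplot object.
#' @export
plot_diversity_groups <- function(diversity, lines) {
  d <- dplyr::inner_join(diversity,
                         dplyr::select(lines, "line_id", "group"),
                         by = "line_id") |>
    dplyr::mutate(group = factor(.data$group,
                                 c("OB", "Low", "Medium", "High")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$pi_relative)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = "Expected inbreeding level",
                  y = expression("Nucleotide diversity " * pi *
                                   " (relative to outbred mean)")) +
    ggplot2::theme_classic()
}

#' Boxplot of relative diversity by extinction class
#'
#' Extinct lines are grouped by when they failed (generation 1, 2, or 3-9)
#' against lines that persisted.
#'
#' @inheritParams plot_diversity_groups
#' @param lines Manifest with `line_id` and `extinction_gen`.
#' @return A ggplot object.
#' @export
plot_extinction_diversity <- function(diversity, lines) {
  d <- dplyr::inner_join(diversity,
                         dplyr::select(lines, "line_id", "extinction_gen"),
                         by = "line_id") |>
    dplyr::mutate(class = dplyr::case_when(
      is.na(.data$extinction_gen) ~ "Survived",
      .data$extinction_gen == 1 ~ "Extinct gen 1",
      .data$extinction_gen == 2 ~ "Extinct gen 2",
      TRUE ~ "Extinct gen 3-9"
    )) |>
    dplyr::mutate(class = factor(.data$class,
                                 c("Extinct gen 1", "Extinct gen 2",
                                   "Extinct gen 3-9", "Survived")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$pi_relative)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = NULL,
                  y = expression("Nucleotide diversity " * pi *
                                   " (relative to outbred mean)")) +
    ggplot2::theme_classic()
}

#' Scatter panels of response measures against each predictor
#'
#' One panel per response measure and predictor (diversity pi or expected
#' F), with the fitted regression line; the structure of the headline
#' correlation figures.
#'
#' @param object A `predictor_comparison` from [compare_predictors()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.predictor_comparison <- function(object, ...) {
  # long layout: (response measure) x (predictor)
  long <- tidyr::pivot_longer(
    dplyr::select(object$data, "line_id", "pi_relative", "expected_f"),
    cols = c("pi_relative", "expected_f"),
    names_to = "predictor", values_to = "x")
  d <- dplyr::inner_join(object$response_values, long, by = "line_id",
                         relationship = "many-to-many")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::facet_grid(response ~ predictor, scales = "free") +
    ggplot2::labs(x = "Predictor value", y = "Evolutionary response") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Viability change per line with variance-sum-law error bars
#'
#' @param deltas Tibble from [viability_change()].
#' @return A ggplot object.
#' @export
plot_viability_change <- function(deltas) {
  ggplot2::ggplot(deltas,
                  ggplot2::aes(x = .data$line_id, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$delta - .data$se,
                                          ymax = .data$delta + .data$se),
                             size = 0.2) +
    ggplot2::facet_wrap(~medium, ncol = 1) +
    ggplot2::labs(x = NULL, y = "Change in egg-to-adult viability") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
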