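# ggplot2 displays for outcome tables, confusion summaries and reliability.

outcome_palette <- c(
  RTP = "#08306b", TP = "#4292c6", TN = "#c6dbef",
  FN = "#a50f15", FP = "#fb6a4a"
)

#' Plot an outcome table as a connection matrix
#'
#' Lower-triangular 14 x 14 matrix of the prefrontal areas in canonical
#' order, tiles coloured by outcome label (robust true positives darkest).
#'
#' @param object A `saf_outcomes` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot saf_outcomes
#' @export
autoplot.saf_outcomes <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(area_a = factor(.data$area_a, levels = pfc_area_order),
           area_b = factor(.data$area_b, levels = pfc_area_order),
           outcome_label = factor(.data$outcome_label,
                                  levels = names(outcome_palette)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$area_a, y = .data$area_b,
                                   fill = .data$outcome_label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = outcome_palette, drop = FALSE,
                               name = "outcome") +
    ggplot2::scale_y_discrete(limits = rev(pfc_area_order)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Tractography vs histology, 91 prefrontal connections") +
    ggplot2::theme_minimal()
}

#' Plot confusion statistics
#'
#' Bar chart of accuracy, sensitivity, specificity and precision for one or
#' more summarized scopes.
#'
#' @param object A `saf_confusion` tibble (one or more rows, e.g.
#'   `dplyr::bind_rows()` of overall and partition summaries).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot saf_confusion
#' @export
autoplot.saf_confusion <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(cols = c("accuracy", "sensitivity", "specificity",
                                 "precision"),
                        names_to = "metric", values_to = "percent")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$percent,
                                   fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}

#' Plot reliability comparisons
#'
#' Mean +/- sd of wDice and bundle adjacency, within- vs between-subject.
#'
#' @param object A `saf_reliability` object, or a list of them to overlay
#'   (e.g. `list(within, between)`).
#' @param ... Further `saf_reliability` objects to overlay.
#' @return A ggplot object.
#' @method autoplot saf_reliability
#' @export
autoplot.saf_reliability <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), "saf_reliability")]
  df <- bind_rows(lapply(c(list(object), extra), function(x) x$report))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$mean,
                                   fill = .data$comparison)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean ± sd") +
    ggplot2::theme_minimal()
}
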