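#' ROC curves of every model in a study run
#'
#' Draws one ROC curve per model from the out-of-fold predictions, with
#' AUCs in the legend, the way the study's discrimination figure presents
#' them.
#'
#' @param object A `study_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_result <- function(object, ...) {
  reserved <- c("subject_id", "fold", "outcome", "subtype")
  cols <- setdiff(names(object$predictions), reserved)
  coords <- purrr::map_dfr(cols, function(col) {
    auc <- roc_auc(object$predictions[[col]], object$predictions$outcome)
    dplyr::mutate(
      roc_coordinates(object$predictions[[col]],
                      object$predictions$outcome),
      model = sprintf("%s (AUC %.3f)", col, auc)
    )
  })
  ggplot2::ggplot(coords,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity,
                               colour = .data$model)) +
    ggplot2::geom_step(linewidth = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Calibration plot of predicted against observed risk
#'
#' Groups subjects into deciles of predicted risk and plots observed event
#' fractions against mean predicted risk, the visual companion of the
#' Hosmer-Lemeshow test.
#'
#' @param data A data frame with risk and outcome columns.
#' @param risk_col,outcome_col Column names.
#' @param groups Number of risk groups.
#' @return A ggplot object.
#' @export
plot_calibration <- function(data, risk_col = "risk",
                             outcome_col = "outcome", groups = 10L) {
  risks <- data[[risk_col]]
  outcomes <- data[[outcome_col]]
  breaks <- unique(quantile(risks, probs = seq(0, 1, length.out = groups + 1)))
  g <- cut(risks, breaks = breaks, include.lowest = TRUE)
  df <- tibble::tibble(risk = risks, outcome = outcomes, group = g) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(predicted = mean(.data$risk),
                     observed = mean(.data$outcome),
                     n = dplyr::n(), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted,
                                   y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "Mean predicted risk", y = "Observed event fraction",
                  size = "Subjects") +
    ggplot2::theme_minimal()
}
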