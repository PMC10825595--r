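# ggplot2 views of diagnoses and evaluation metrics.

#' Plot the belief state of a diagnosis
#'
#' Horizontal bars of confirmed-symptom fraction per disorder hypothesis,
#' coloured by status. The conjunctive rule means only a full bar
#' (fraction 1) is a diagnosis; partial bars show near-misses.
#'
#' @param object A `vriksha_diagnosis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vriksha_diagnosis
#' @export
autoplot.vriksha_diagnosis <- function(object, ...) {
  df <- tidy(object)
  df$disorder_id <- factor(df$disorder_id, levels = rev(df$disorder_id))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$confirmed_fraction, y = .data$disorder_id, fill = .data$status
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::scale_fill_manual(values = c(
      confirmed = "#1b9e77", open = "#7570b3", rejected = "#d95f02"
    )) +
    ggplot2::labs(
      x = "confirmed symptom fraction", y = NULL, fill = "status",
      title = "Belief state by disorder hypothesis"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation confusion matrix
#'
#' True disorder vs the engine's primary conclusion, as a tile plot with
#' counts.
#'
#' @param object A `vriksha_metrics`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vriksha_metrics
#' @export
autoplot.vriksha_metrics <- function(object, ...) {
  df <- object$confusion
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$predicted, y = .data$true_disorder_id, fill = .data$n
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(
      x = "predicted (primary)", y = "true disorder",
      title = sprintf("Confusion over %d cases (accuracy %.2f)",
        object$n_cases, object$accuracy)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
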