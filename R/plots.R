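## ggplot2 views of the result types ----------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a tracking session
#'
#' Floor-plane (x, z) view of the three device trajectories.
#'
#' @param object A `vr_session`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vr_session <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   colour = .data$device)) +
    ggplot2::geom_path(alpha = 0.7, na.rm = TRUE) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste("Session", session_subject(object)),
      x = "x (m)", y = "z (m)", colour = "device"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a correlation screen
#'
#' Heatmap of Pearson r over the feature x measure grid, with significant
#' pairs (at the screen's alpha) marked.
#'
#' @param object A `vr_screen` from [correlation_screen()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vr_screen <- function(object, ...) {
  df <- as_tibble(object)
  df$feature <- factor(df$feature, levels = rev(kin_features()))
  df$measure <- factor(df$measure, levels = unique(df$measure))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure, y = .data$feature,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = dplyr::if_else(.data$significant, "*", "")),
      na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = sprintf("Correlation screen (* p < %g)",
                                  attr(object, "alpha"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a stepwise fit
#'
#' Coefficient plot of the retained predictors; an empty model produces an
#' annotated empty panel.
#'
#' @param object A `stepwise_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.stepwise_fit <- function(object, ...) {
  if (object$empty_model) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0,
                          label = "no predictors retained") +
        ggplot2::theme_void() +
        ggplot2::labs(title = object$outcome)
    )
  }
  df <- object$terms
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_col() +
    ggplot2::labs(
      title = sprintf("%s (R² = %.3f)", object$outcome,
                      object$r.squared),
      x = "coefficient", y = NULL) +
    ggplot2::theme_minimal()
}
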