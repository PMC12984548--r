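#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pen trajectory
#'
#' Draws the planar pen path, on-paper strokes as solid segments and
#' in-air transit as faint dashed segments.
#'
#' @param object A `pen_trajectory`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pen_trajectory <- function(object, ...) {
  if (nrow(object) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "empty recording") +
             ggplot2::theme_void())
  }
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(state = factor(ifelse(.data$pen_status == 1L, "on paper", "in air"),
                                 levels = c("on paper", "in air")))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = 1)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$state, linetype = .data$state,
                                    alpha = .data$state)) +
    ggplot2::scale_alpha_manual(values = c(`on paper` = 1, `in air` = 0.35)) +
    ggplot2::scale_linetype_manual(values = c(`on paper` = "solid", `in air` = "dashed")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (device units)", y = "y (device units)",
                  colour = NULL, linetype = NULL, alpha = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an empty-recording census
#'
#' Stacked per-task bar chart of empty recordings by class.
#'
#' @param object A `task_census`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.task_census <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("healthy_empty", "patient_empty"),
                        names_to = "class", values_to = "count") |>
    dplyr::mutate(class = sub("_empty$", "", .data$class))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$task_id), .data$count,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "task", y = "empty recordings", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot sweep accuracies by classifier
#'
#' @param object A `sweep_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$classifier, .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(ggplot2::vars(.data$normalization)) +
    ggplot2::labs(x = NULL, y = "accuracy (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
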