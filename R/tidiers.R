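#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sweep result
#'
#' One row per evaluated configuration with its fold-averaged metrics.
#'
#' @param x A `sweep_result`.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.sweep_result <- function(x, ...) x$table

#' One-row summary of a sweep
#'
#' @param x A `sweep_result`.
#' @param ... Ignored.
#' @return A tibble with the configuration count, best accuracy and the
#'   best configuration's labels.
#' @export
glance.sweep_result <- function(x, ...) {
  best <- x$table[which.max(x$table$accuracy), ]
  tibble::tibble(
    n_configurations = nrow(x$table),
    best_accuracy = best$accuracy,
    best_classifier = best$classifier,
    best_selector = best$feature_selection,
    best_k = best$k,
    mean_accuracy = mean(x$table$accuracy)
  )
}

#' Tidy a nested cross-validation result
#'
#' @param x A `nested_cv_result`.
#' @param ... Ignored.
#' @return The per-model metrics tibble.
#' @export
tidy.nested_cv_result <- function(x, ...) x$metrics

#' One-row summary of a nested cross-validation run
#'
#' @param x A `nested_cv_result`.
#' @param ... Ignored.
#' @return A tibble with fold counts and the best model's accuracy.
#' @export
glance.nested_cv_result <- function(x, ...) {
  best <- x$metrics[which.max(x$metrics$accuracy), ]
  tibble::tibble(
    outer_folds = x$config$outer_folds,
    inner_folds = x$config$inner_folds,
    n_models = nrow(x$metrics),
    best_model = best$model,
    best_accuracy = best$accuracy
  )
}
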