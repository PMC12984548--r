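#' Canonical matrix column name for a (task, feature) pair
#' @param task_id Integer task id(s).
#' @param feature Feature name(s).
#' @return Character vector like `"T09_SNRCE_X"`.
#' @export
matrix_column_name <- function(task_id, feature) {
  sprintf("T%02d_%s", as.integer(task_id), feature)
}

#' Parse canonical matrix column names
#' @param columns Character vector of `T{task}_{feature}` names.
#' @return Tibble with `column`, `task_id`, `feature`.
#' @export
parse_matrix_columns <- function(columns) {
  m <- stringr::str_match(columns, "^T(\\d{2})_(.+)$")
  bad <- which(is.na(m[, 1]) | !m[, 3] %in% feature_names())
  if (length(bad) > 0L) {
    stop(sprintf("unparseable feature column name: %s", columns[bad[1]]), call. = FALSE)
  }
  tibble::tibble(column = columns, task_id = as.integer(m[, 2]), feature = m[, 3])
}

#' Assemble the subject x (task x feature) matrix
#'
#' Pivots per-recording feature vectors into a wide cohort matrix with
#' canonical task-major columns (48 feature columns per task in
#' [feature_names()] order). Recordings absent from the input, like
#' all-NA vectors from empty recordings, appear as NA blocks: missingness
#' is carried as NA and is never silently zero.
#'
#' @param feature_tbl Output of [extract_cohort_features()].
#' @param task_set Integer task ids defining the column universe
#'   (defaults to the tasks present).
#' @return A tibble of class `feature_matrix` with columns subject_id,
#'   label, then `48 * length(task_set)` feature columns.
#' @export
build_feature_matrix <- function(feature_tbl, task_set = NULL) {
  if (is.null(task_set)) task_set <- sort(unique(feature_tbl$task_id))
  task_set <- sort(as.integer(task_set))
  dup <- feature_tbl |>
    dplyr::count(.data$subject_id, .data$task_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop(sprintf("duplicate (subject, task) feature vector: %s task %d",
                 dup$subject_id[1], dup$task_id[1]), call. = FALSE)
  }
  long <- feature_tbl |>
    dplyr::filter(.data$task_id %in% task_set) |>
    tidyr::pivot_longer(dplyr::all_of(feature_names()),
                        names_to = "feature", values_to = "value") |>
    dplyr::mutate(column = matrix_column_name(.data$task_id, .data$feature))
  canonical <- as.vector(vapply(task_set, function(t) {
    matrix_column_name(t, feature_names())
  }, character(48L)))
  wide <- long |>
    dplyr::select("subject_id", "label", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  for (col in setdiff(canonical, names(wide))) wide[[col]] <- NA_real_
  out <- wide |>
    dplyr::select("subject_id", "label", dplyr::all_of(canonical)) |>
    dplyr::arrange(.data$subject_id)
  class(out) <- c("feature_matrix", class(out))
  out
}

feature_matrix_columns <- function(matrix) {
  setdiff(names(matrix), c("subject_id", "label"))
}

#' Impute missing cells from a training partition
#'
#' Replaces NA cells by the per-column median computed over the
#' designated reference (training) rows only, so test rows never
#' influence the statistics. Columns entirely missing in the reference
#' are filled with 0.
#'
#' @param matrix A `feature_matrix`.
#' @param reference_rows Integer row indices of the fit partition
#'   (defaults to all rows).
#' @return The matrix with NAs replaced.
#' @export
impute_missing <- function(matrix, reference_rows = seq_len(nrow(matrix))) {
  stopifnot(length(reference_rows) > 0L)
  cols <- feature_matrix_columns(matrix)
  for (col in cols) {
    v <- matrix[[col]]
    if (!anyNA(v)) next
    med <- stats::median(v[reference_rows], na.rm = TRUE)
    if (is.na(med)) med <- 0
    v[is.na(v)] <- med
    matrix[[col]] <- v
  }
  matrix
}

#' Normalization specification
#'
#' @param strategy One of `"unnormalized"`, `"minmax"`, `"zscore"`.
#' @return A `normalization_spec` list (fit statistics are attached by
#'   [fit_apply_normalizer()]).
#' @export
normalization_spec <- function(strategy = c("unnormalized", "minmax", "zscore")) {
  strategy <- match.arg(strategy)
  structure(list(strategy = strategy, stats = NULL), class = "normalization_spec")
}

#' Fit a normalizer on designated rows and apply it to all rows
#'
#' Min-max maps each column through (v - min) / (max - min) with the
#' statistics taken from `fit_rows` (values outside the fit range land
#' outside `[0, 1]`); z-score maps through (v - mean) / sd. Columns
#' constant on the fit rows transform to all zeros. The unnormalized
#' strategy is the identity.
#'
#' @param matrix A `feature_matrix` (imputed; NAs pass through untouched).
#' @param spec A [normalization_spec()].
#' @param fit_rows Row indices the statistics are computed from.
#' @return List with `matrix` (transformed) and `spec` (with fitted
#'   per-column statistics).
#' @export
fit_apply_normalizer <- function(matrix, spec = normalization_spec(),
                                 fit_rows = seq_len(nrow(matrix))) {
  stopifnot(length(fit_rows) > 0L)
  cols <- feature_matrix_columns(matrix)
  if (spec$strategy == "unnormalized") {
    spec$stats <- NULL
    return(list(matrix = matrix, spec = spec))
  }
  stats_tbl <- purrr::map(cols, function(col) {
    v <- matrix[[col]][fit_rows]
    if (spec$strategy == "minmax") {
      c(a = min(v, na.rm = TRUE), b = max(v, na.rm = TRUE))
    } else {
      c(a = mean(v, na.rm = TRUE), b = stats::sd(v, na.rm = TRUE))
    }
  })
  names(stats_tbl) <- cols
  for (col in cols) {
    st <- stats_tbl[[col]]
    v <- matrix[[col]]
    if (spec$strategy == "minmax") {
      rng <- st["b"] - st["a"]
      matrix[[col]] <- if (!is.finite(rng) || rng == 0) rep(0, length(v)) else (v - st["a"]) / rng
    } else {
      matrix[[col]] <- if (!is.finite(st["b"]) || st["b"] == 0) rep(0, length(v)) else (v - st["a"]) / st["b"]
    }
  }
  spec$stats <- stats_tbl
  list(matrix = matrix, spec = spec)
}

#' Restrict a feature matrix to a task subset
#'
#' Keeps only the 48-column blocks of the listed tasks, preserving
#' canonical task-major order.
#'
#' @param matrix A `feature_matrix`.
#' @param task_list Integer task ids, a subset of the matrix tasks.
#' @return The restricted `feature_matrix`.
#' @export
reduce_tasks <- function(matrix, task_list) {
  info <- parse_matrix_columns(feature_matrix_columns(matrix))
  present <- sort(unique(info$task_id))
  unknown <- setdiff(as.integer(task_list), present)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown task id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  keep_tasks <- sort(as.integer(task_list))
  keep <- as.vector(vapply(keep_tasks, function(t) {
    matrix_column_name(t, feature_names())
  }, character(48L)))
  out <- matrix |> dplyr::select("subject_id", "label", dplyr::all_of(keep))
  class(out) <- unique(c("feature_matrix", class(out)))
  out
}

#' The published 14-task reduced set
#'
#' Task ids retained after excluding tasks with many empty recordings
#' and low selection frequency from the 25-task battery.
#'
#' @return Integer vector of 14 task ids.
#' @export
reduced_task_set <- function() {
  c(1L, 3L, 4L, 5L, 7L, 9L, 10L, 11L, 13L, 14L, 16L, 17L, 23L, 25L)
}
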