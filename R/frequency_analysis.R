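#' Published empty-recording census of the 25-task battery
#'
#' Per-task counts of empty (or absent) recordings in the public
#' DARWIN cohort (89 patients, 85 controls), split by class: 153 empty
#' recordings in total, 54 from healthy controls and 99 from patients.
#' Useful as reference input for the task-reduction analyses and as a
#' fixture for census arithmetic.
#'
#' @return Tibble with task_id, total_empty, healthy_empty, patient_empty.
#' @export
darwin_empty_census <- function() {
  tibble::tribble(
    ~task_id, ~total_empty, ~healthy_empty, ~patient_empty,
    1L, 0L, 0L, 0L,
    2L, 3L, 3L, 0L,
    3L, 2L, 1L, 1L,
    4L, 1L, 1L, 0L,
    5L, 1L, 1L, 0L,
    6L, 3L, 2L, 1L,
    7L, 2L, 2L, 0L,
    8L, 4L, 4L, 0L,
    9L, 3L, 2L, 1L,
    10L, 4L, 2L, 2L,
    11L, 4L, 2L, 2L,
    12L, 5L, 3L, 2L,
    13L, 6L, 2L, 4L,
    14L, 6L, 2L, 4L,
    15L, 5L, 2L, 3L,
    16L, 4L, 2L, 2L,
    17L, 4L, 2L, 2L,
    18L, 4L, 2L, 2L,
    19L, 28L, 6L, 22L,
    20L, 10L, 2L, 8L,
    21L, 13L, 3L, 10L,
    22L, 10L, 2L, 8L,
    23L, 9L, 2L, 7L,
    24L, 10L, 2L, 8L,
    25L, 12L, 2L, 10L
  )
}

#' Published per-task selection frequencies
#'
#' Counts of selected features per task among the best-performing
#' configurations, for each normalization strategy of the 25-task sweep.
#'
#' @return Tibble with task_id, unnormalized, zscore, minmax.
#' @export
darwin_task_frequencies <- function() {
  tibble::tribble(
    ~task_id, ~unnormalized, ~zscore, ~minmax,
    1L, 11L, 11L, 11L,
    2L, 14L, 14L, 14L,
    3L, 13L, 13L, 13L,
    4L, 16L, 16L, 16L,
    5L, 13L, 13L, 13L,
    6L, 13L, 13L, 13L,
    7L, 33L, 23L, 33L,
    8L, 31L, 30L, 31L,
    9L, 97L, 109L, 97L,
    10L, 20L, 19L, 20L,
    11L, 15L, 15L, 15L,
    12L, 16L, 16L, 16L,
    13L, 19L, 19L, 19L,
    14L, 19L, 19L, 19L,
    15L, 0L, 0L, 0L,
    16L, 16L, 16L, 16L,
    17L, 9L, 9L, 9L,
    18L, 10L, 10L, 10L,
    19L, 7L, 7L, 7L,
    20L, 13L, 13L, 13L,
    21L, 11L, 11L, 11L,
    22L, 4L, 4L, 4L,
    23L, 17L, 16L, 17L,
    24L, 12L, 13L, 12L,
    25L, 11L, 11L, 11L
  )
}

# Best configuration (by accuracy) per strategy and selector: the
# top-rule whose arithmetic matches the published tallies (feature
# averages in quarters = / 4 selectors; task counts ~ 4 x k).
top_selection_records <- function(sweep, top_n = 1L) {
  sel <- sweep$selections |>
    dplyr::mutate(record_id = paste(.data$normalization, .data$selector, .data$k))
  best <- sweep$table |>
    dplyr::mutate(selector = display_selector_inverse(.data$feature_selection)) |>
    dplyr::group_by(.data$normalization, .data$selector) |>
    dplyr::slice_max(.data$accuracy, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(record_id = paste(.data$normalization, .data$selector, .data$k))
  sel |> dplyr::filter(.data$record_id %in% best$record_id)
}

display_selector_inverse <- function(x) {
  map <- c("RF Importance" = "rf_importance", "XGB Importance" = "xgb_weight",
           "L1 Regularization" = "l1", "RFE Random Forest" = "rfe_rf")
  unname(map[x])
}

# Selected features of one configuration = union semantics are not used:
# each fold's selections are pooled and de-duplicated per configuration,
# giving the configuration's selected set.
configuration_selected_sets <- function(records) {
  records |>
    dplyr::group_by(.data$normalization, .data$selector, .data$k) |>
    dplyr::summarise(
      selected = list(unique(unlist(.data$selected_features))),
      .groups = "drop"
    )
}

#' Task-level selection frequencies among top configurations
#'
#' For the best configuration per (strategy, selector), counts how many
#' selected feature columns belong to each task, per normalization
#' strategy.
#'
#' @param sweep A `sweep_result`.
#' @param task_set Task universe for zero-filled rows.
#' @return Tibble with task_id and one count column per strategy.
#' @export
tally_task_frequencies <- function(sweep, task_set = NULL) {
  sets <- configuration_selected_sets(top_selection_records(sweep))
  if (is.null(task_set)) {
    all_feats <- unique(unlist(sets$selected))
    task_set <- if (length(all_feats)) sort(unique(parse_matrix_columns(all_feats)$task_id)) else integer()
  }
  strategies <- unique(sweep$selections$normalization)
  counts <- purrr::map_dfr(strategies, function(strat) {
    feats <- unlist(sets$selected[sets$normalization == strat])
    tab <- if (length(feats)) parse_matrix_columns(feats) |>
      dplyr::count(.data$task_id) else tibble::tibble(task_id = integer(), n = integer())
    tibble::tibble(task_id = as.integer(task_set)) |>
      dplyr::left_join(tab, by = "task_id") |>
      dplyr::mutate(normalization = strat, n = dplyr::coalesce(.data$n, 0L))
  })
  counts |>
    tidyr::pivot_wider(names_from = "normalization", values_from = "n") |>
    dplyr::arrange(.data$task_id)
}

#' Feature-level selection frequencies among top configurations
#'
#' Per-feature selection counts (a feature counts once per task it is
#' selected in) averaged over the selectors, per strategy, plus the
#' overall average and the share of selections contributed by the
#' extended (newly introduced) descriptor block.
#'
#' @param sweep A `sweep_result`.
#' @return List with `table` (feature, per-strategy average, overall
#'   average) and `new_feature_share` (percent of all selections that
#'   are extended features).
#' @export
tally_feature_frequencies <- function(sweep) {
  sets <- configuration_selected_sets(top_selection_records(sweep))
  strategies <- unique(sets$normalization)
  baseline <- feature_names()[1:18]
  per_strategy <- purrr::map_dfr(strategies, function(strat) {
    sub <- sets[sets$normalization == strat, ]
    n_selectors <- nrow(sub)
    feats <- unlist(sub$selected)
    parsed <- parse_matrix_columns(feats)
    parsed |>
      dplyr::count(.data$feature) |>
      dplyr::mutate(normalization = strat, avg = .data$n / n_selectors) |>
      dplyr::select("feature", "normalization", "avg")
  })
  table <- tidyr::expand_grid(feature = feature_names(),
                              normalization = strategies) |>
    dplyr::left_join(per_strategy, by = c("feature", "normalization")) |>
    dplyr::mutate(avg = dplyr::coalesce(.data$avg, 0)) |>
    tidyr::pivot_wider(names_from = "normalization", values_from = "avg") |>
    dplyr::mutate(overall_average = rowMeans(dplyr::across(dplyr::all_of(strategies)))) |>
    dplyr::arrange(dplyr::desc(.data$overall_average))
  all_feats <- parse_matrix_columns(unlist(sets$selected))
  share <- if (nrow(all_feats) > 0) {
    100 * mean(!all_feats$feature %in% baseline)
  } else NA_real_
  list(table = table, new_feature_share = share)
}

#' Correlation between task missingness and selection frequency
#'
#' Pearson correlation between per-task empty-recording totals and
#' per-task selection frequencies of one strategy column.
#'
#' @param census Tibble with task_id and total_empty (e.g.
#'   [darwin_empty_census()] or [census_empty_files()] output).
#' @param frequency_table Tibble with task_id and strategy columns (e.g.
#'   [darwin_task_frequencies()] or [tally_task_frequencies()] output).
#' @param column Strategy column name (default `"unnormalized"`).
#' @return Pearson r, or NA with a warning when either vector is
#'   constant.
#' @export
empty_vs_frequency_correlation <- function(census, frequency_table,
                                           column = "unnormalized") {
  joined <- dplyr::inner_join(
    census |> dplyr::select("task_id", "total_empty"),
    frequency_table |> dplyr::select("task_id", dplyr::all_of(column)),
    by = "task_id"
  )
  if (nrow(joined) != nrow(census) || nrow(joined) != nrow(frequency_table)) {
    stop("census and frequency table must cover identical task sets", call. = FALSE)
  }
  x <- joined$total_empty
  y <- joined[[column]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Task-reduction proposal
#'
#' Applies the exclusion rule -- drop tasks with more than
#' `empty_cutoff` empty recordings AND a selection frequency below
#' `freq_cutoff` -- and reports it alongside the published 14-task
#' constant, flagging any divergence between the two.
#'
#' @param census Census tibble (task_id, total_empty).
#' @param frequency_table Frequency tibble (task_id + strategy columns).
#' @param empty_cutoff Empty-recording cutoff (default 10, exclusive).
#' @param freq_cutoff Selection-frequency cutoff (default 12, exclusive).
#' @param column Strategy column used for frequencies.
#' @return List with `rule_tasks` (retained under the rule),
#'   `published_tasks` (the shipped constant), `diverges` (logical) and
#'   `divergence` (tasks in exactly one of the two lists).
#' @export
propose_task_reduction <- function(census, frequency_table,
                                   empty_cutoff = 10, freq_cutoff = 12,
                                   column = "unnormalized") {
  joined <- dplyr::inner_join(
    census |> dplyr::select("task_id", "total_empty"),
    frequency_table |> dplyr::select("task_id", dplyr::all_of(column)),
    by = "task_id"
  )
  excluded <- joined$task_id[joined$total_empty > empty_cutoff &
                               joined[[column]] < freq_cutoff]
  rule_tasks <- sort(setdiff(joined$task_id, excluded))
  published <- reduced_task_set()
  divergence <- sort(c(setdiff(rule_tasks, published), setdiff(published, rule_tasks)))
  list(rule_tasks = rule_tasks, published_tasks = published,
       diverges = length(divergence) > 0L, divergence = divergence)
}
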