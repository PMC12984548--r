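CLASS_LEVELS <- c("healthy", "patient")

as_label_factor <- function(y) factor(as.character(y), levels = CLASS_LEVELS)

feature_design <- function(matrix, columns = feature_matrix_columns(matrix)) {
  X <- as.matrix(matrix[, columns, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Rank features by random-forest Gini importance
#'
#' Mean decrease in Gini impurity from a random forest fit on the full
#' design, normalized to sum 1. Ties (including all-constant designs)
#' are broken by canonical column order downstream.
#'
#' @param X Numeric design matrix (fully imputed) with column names.
#' @param y Binary label vector/factor (`healthy` / `patient`).
#' @param seed Integer seed; the ranking is deterministic given it.
#' @param num_trees Forest size.
#' @return A tibble (`importance_ranking`) with `feature`, `score`,
#'   sorted by descending score with index tie-break.
#' @export
rank_rf_importance <- function(X, y, seed = 1L, num_trees = 300L) {
  y <- as_label_factor(y)
  if (length(unique(y)) < 2L) stop("labels are constant", call. = FALSE)
  set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = y, ntree = num_trees)
  scores <- fit$importance[, "MeanDecreaseGini"]
  if (sum(scores) > 0) scores <- scores / sum(scores)
  make_ranking(colnames(X), scores)
}

#' Rank features by boosted-tree split counts
#'
#' "Weight" importance: the number of times each feature is used as a
#' split across all boosting rounds, normalized; features never split on
#' score 0.
#'
#' @inheritParams rank_rf_importance
#' @param nrounds Boosting rounds.
#' @return An `importance_ranking` tibble.
#' @export
rank_xgb_weight <- function(X, y, seed = 1L, nrounds = 50L) {
  y <- as_label_factor(y)
  if (length(unique(y)) < 2L) stop("labels are constant", call. = FALSE)
  set.seed(seed)
  fit <- xgboost::xgboost(
    x = X, y = y, objective = "binary:logistic", nrounds = nrounds,
    max_depth = 4L, learning_rate = 0.1, nthreads = 1L, verbosity = 0
  )
  imp <- xgboost::xgb.importance(model = fit)
  scores <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (!is.null(imp) && nrow(imp) > 0L) {
    scores[imp$Feature] <- imp$Frequency
  }
  make_ranking(colnames(X), scores)
}

#' Rank features by L1-penalized logistic-regression coefficients
#'
#' Absolute coefficients of a lasso logistic fit at a fixed penalty;
#' shrinkage drives many scores to exactly zero.
#'
#' @inheritParams rank_rf_importance
#' @param lambda L1 penalty strength (> 0).
#' @return An `importance_ranking` tibble.
#' @export
rank_l1 <- function(X, y, lambda = 0.05) {
  stopifnot(lambda > 0)
  y <- as_label_factor(y)
  if (length(unique(y)) < 2L) stop("labels are constant", call. = FALSE)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = TRUE)
  coefs <- as.numeric(stats::coef(fit))[-1]
  make_ranking(colnames(X), abs(coefs))
}

make_ranking <- function(features, scores) {
  out <- tibble::tibble(feature = features, score = as.numeric(scores)) |>
    dplyr::mutate(.index = dplyr::row_number()) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$.index) |>
    dplyr::select("feature", "score")
  class(out) <- c("importance_ranking", class(out))
  out
}

#' Top-k features of an importance ranking
#'
#' Ties are broken by canonical column order (the order features entered
#' the design matrix).
#'
#' @param ranking An `importance_ranking`.
#' @param k Number of features, 1 <= k <= nrow(ranking).
#' @return Character vector of k feature names.
#' @export
select_top_k <- function(ranking, k) {
  if (k <= 0L) stop("k must be positive", call. = FALSE)
  if (k > nrow(ranking)) stop("k exceeds the number of ranked features", call. = FALSE)
  ranking$feature[seq_len(k)]
}

#' Recursive feature elimination with a random-forest ranker
#'
#' Repeatedly fits a forest, ranks by Gini importance, and drops the
#' lowest-ranked `step` fraction (at least one feature) until exactly k
#' features remain.
#'
#' @inheritParams rank_rf_importance
#' @param k Target feature count.
#' @param step Fraction of current features eliminated per round, in (0, 1).
#' @return Character vector of k selected feature names (canonical order).
#' @export
select_rfe <- function(X, y, k, step = 0.2, seed = 1L) {
  stopifnot(step > 0, step < 1)
  if (k > ncol(X)) stop("k exceeds the number of features", call. = FALSE)
  current <- colnames(X)
  round_i <- 0L
  while (length(current) > k) {
    round_i <- round_i + 1L
    ranking <- rank_rf_importance(X[, current, drop = FALSE], y,
                                  seed = seed + round_i)
    n_drop <- min(max(1L, floor(step * length(current))), length(current) - k)
    current <- ranking$feature[seq_len(length(current) - n_drop)]
  }
  colnames(X)[colnames(X) %in% current]
}

#' Selector configuration
#'
#' @param method One of `"rf_importance"`, `"xgb_weight"`, `"l1"`,
#'   `"rfe_rf"`.
#' @param k Target number of selected features.
#' @param lambda L1 penalty (l1 only).
#' @param step RFE elimination fraction (rfe_rf only).
#' @return A `selector_config` list.
#' @export
selector_config <- function(method = c("rf_importance", "xgb_weight", "l1", "rfe_rf"),
                            k = 100L, lambda = 0.05, step = 0.2) {
  method <- match.arg(method)
  stopifnot(k >= 1L, lambda > 0, step > 0, step < 1)
  structure(list(method = method, k = as.integer(k), lambda = lambda, step = step),
            class = "selector_config")
}

select_features <- function(X, y, selector, seed) {
  k <- min(selector$k, ncol(X))
  switch(selector$method,
    rf_importance = select_top_k(rank_rf_importance(X, y, seed = seed), k),
    xgb_weight = select_top_k(rank_xgb_weight(X, y, seed = seed), k),
    l1 = select_top_k(rank_l1(X, y, lambda = selector$lambda), k),
    rfe_rf = select_rfe(X, y, k = k, step = selector$step, seed = seed)
  )
}

# ---- base classifiers ---------------------------------------------------

default_hyper_grids <- function() {
  list(
    svm = expand.grid(kernel = c("linear", "radial"), cost = c(0.1, 1, 10),
                      stringsAsFactors = FALSE),
    rf = expand.grid(ntree = c(100L, 300L)),
    lr = expand.grid(lambda = c(10, 1, 0.1)),
    mlp = expand.grid(size = c(50L, 100L)),
    xgb = expand.grid(max_depth = c(3L, 5L), eta = 0.1)
  )
}

fit_base_model <- function(name, X, y, params, seed) {
  y <- as_label_factor(y)
  set.seed(seed)
  model <- switch(name,
    svm = e1071::svm(x = X, y = y, kernel = params$kernel, cost = params$cost,
                     probability = TRUE, scale = FALSE),
    rf = randomForest::randomForest(x = X, y = y, ntree = params$ntree),
    lr = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = params$lambda, standardize = FALSE),
    mlp = nnet::nnet(x = X, y = as.integer(y == "patient"), size = params$size,
                     decay = 0.1, maxit = 200, MaxNWts = 1e6, trace = FALSE,
                     entropy = TRUE),
    xgb = xgboost::xgboost(x = X, y = y, objective = "binary:logistic",
                           nrounds = 100L, max_depth = params$max_depth,
                           learning_rate = params$eta, nthreads = 1L,
                           verbosity = 0),
    stop(sprintf("unknown classifier '%s'", name), call. = FALSE)
  )
  list(name = name, model = model, params = params,
       features = colnames(X))
}

predict_base_model <- function(fit, X) {
  X <- X[, fit$features, drop = FALSE]
  p_patient <- switch(fit$name,
    svm = {
      pr <- attr(stats::predict(fit$model, X, probability = TRUE), "probabilities")
      pr[, "patient"]
    },
    rf = stats::predict(fit$model, X, type = "prob")[, "patient"],
    lr = as.numeric(stats::predict(fit$model, X, type = "response")),
    mlp = as.numeric(stats::predict(fit$model, X)),
    xgb = as.numeric(stats::predict(fit$model, X, type = "response"))
  )
  p_patient <- pmin(pmax(p_patient, 0), 1)
  prob <- cbind(healthy = 1 - p_patient, patient = p_patient)
  label <- factor(ifelse(p_patient >= 0.5, "patient", "healthy"),
                  levels = CLASS_LEVELS)
  list(prob = prob, label = label)
}

stratified_folds <- function(y, n_folds, seed) {
  y <- as_label_factor(y)
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

inner_cv_tune <- function(name, X, y, grid, n_folds, seed) {
  folds <- stratified_folds(y, n_folds, seed)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    params <- grid[g, , drop = FALSE]
    fold_acc <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      te <- !tr
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- fit_base_model(name, X[tr, , drop = FALSE], y[tr], params,
                            seed = seed + 1000L * g + f)
      pred <- predict_base_model(fit, X[te, , drop = FALSE])
      mean(pred$label == y[te])
    }, numeric(1))
    mean(fold_acc, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(acc)
  list(params = grid[best, , drop = FALSE], inner_score = acc[best])
}

# ---- voting -------------------------------------------------------------

#' Soft-vote member probability distributions
#'
#' Equal-weight average of the member class distributions; the predicted
#' label is the arg-max, with an exact 50/50 tie resolved towards the
#' positive (patient) class.
#'
#' @param member_probabilities List of length-2 numeric vectors
#'   (named `healthy`, `patient`), or a matrix with those columns.
#' @return List with `prob` (named length-2 vector) and `label`.
#' @export
soft_vote <- function(member_probabilities) {
  if (is.list(member_probabilities)) {
    member_probabilities <- do.call(rbind, member_probabilities)
  }
  if (any(abs(rowSums(member_probabilities) - 1) > 1e-6)) {
    stop("member probabilities must sum to 1", call. = FALSE)
  }
  prob <- colMeans(member_probabilities)[CLASS_LEVELS]
  label <- if (prob["patient"] >= prob["healthy"]) "patient" else "healthy"
  list(prob = prob, label = factor(label, levels = CLASS_LEVELS))
}

#' Hard-vote member labels
#'
#' Majority label over the members; a tie is broken towards the class
#' with the larger mean soft probability, then towards the patient class.
#'
#' @param member_labels Character/factor member predictions.
#' @param member_probabilities Optional list/matrix of member class
#'   distributions used only for tie-breaking.
#' @return Factor label.
#' @export
hard_vote <- function(member_labels, member_probabilities = NULL) {
  votes <- table(factor(as.character(member_labels), levels = CLASS_LEVELS))
  if (votes["patient"] != votes["healthy"]) {
    label <- names(votes)[which.max(votes)]
  } else if (!is.null(member_probabilities)) {
    label <- as.character(soft_vote(member_probabilities)$label)
  } else {
    label <- "patient"
  }
  factor(label, levels = CLASS_LEVELS)
}

#' Per-fold dynamic ensemble membership and predictions
#'
#' Members are the base models whose inner-CV score meets the membership
#' threshold (default: the mean of the base scores); when none qualifies
#' the single best model stands alone. The soft ensemble averages member
#' probabilities; the hard ensemble majority-votes member labels over
#' the same member set, applied when the soft ensemble's mean top-class
#' probability meets `escalation_threshold` (default 0, always on).
#'
#' @param fold_predictions Named list (per base model) of
#'   [predict_base_model()]-style lists with `prob` (n x 2 matrix) and
#'   `label`.
#' @param inner_scores Named numeric inner-CV scores of the base models.
#' @param membership_threshold Score cut-off; default mean of scores.
#' @param escalation_threshold Soft-score gate for the hard ensemble.
#' @return List with `members`, `threshold`, `soft` and `hard`
#'   prediction lists (each with `prob`/`label` for all rows).
#' @export
dynamic_ensemble <- function(fold_predictions, inner_scores,
                             membership_threshold = NULL,
                             escalation_threshold = 0) {
  stopifnot(length(fold_predictions) >= 1L)
  if (is.null(membership_threshold)) membership_threshold <- mean(inner_scores)
  members <- names(inner_scores)[inner_scores >= membership_threshold]
  if (length(members) == 0L) members <- names(which.max(inner_scores))
  n <- nrow(fold_predictions[[1]]$prob)
  soft_prob <- matrix(0, n, 2, dimnames = list(NULL, CLASS_LEVELS))
  soft_label <- character(n)
  hard_label <- character(n)
  for (i in seq_len(n)) {
    probs <- lapply(members, function(m) fold_predictions[[m]]$prob[i, ])
    sv <- soft_vote(probs)
    soft_prob[i, ] <- sv$prob
    soft_label[i] <- as.character(sv$label)
    if (max(sv$prob) >= escalation_threshold) {
      labels <- vapply(members, function(m) as.character(fold_predictions[[m]]$label[i]),
                       character(1))
      hard_label[i] <- as.character(hard_vote(labels, probs))
    } else {
      hard_label[i] <- soft_label[i]
    }
  }
  list(
    members = members, threshold = membership_threshold,
    soft = list(prob = soft_prob, label = factor(soft_label, levels = CLASS_LEVELS)),
    hard = list(prob = soft_prob, label = factor(hard_label, levels = CLASS_LEVELS))
  )
}

# ---- metrics ------------------------------------------------------------

fold_metric_row <- function(pred, truth) {
  truth <- as_label_factor(truth)
  pred <- as_label_factor(pred)
  tp <- sum(pred == "patient" & truth == "patient")
  fn <- sum(pred == "healthy" & truth == "patient")
  tn <- sum(pred == "healthy" & truth == "healthy")
  fp <- sum(pred == "patient" & truth == "healthy")
  acc <- (tp + tn) / length(truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1_pos <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  f1_neg <- if (2 * tn + fn + fp > 0) 2 * tn / (2 * tn + fn + fp) else NA_real_
  f1 <- mean(c(f1_pos, f1_neg), na.rm = TRUE)
  c(accuracy = acc, f1 = f1, sensitivity = sens, specificity = spec)
}

#' Fold-averaged classification metrics
#'
#' Accuracy, macro-averaged F1, sensitivity (patient recall) and
#' specificity (healthy recall), each computed per fold, averaged over
#' folds and reported in percent, plus the standard deviation of the
#' per-fold accuracies (percentage points). A fold containing a single
#' truth class has its sensitivity or specificity flagged undefined and
#' excluded from that mean.
#'
#' @param predictions Factor/character predicted labels.
#' @param truth Matching true labels.
#' @param fold Integer fold assignment of each observation.
#' @return A one-row tibble: accuracy, f1, sensitivity, specificity,
#'   std_accuracy.
#' @export
compute_metrics <- function(predictions, truth, fold) {
  stopifnot(length(predictions) == length(truth), length(truth) == length(fold))
  per_fold <- t(vapply(sort(unique(fold)), function(f) {
    idx <- fold == f
    fold_metric_row(predictions[idx], truth[idx])
  }, numeric(4)))
  tibble::tibble(
    accuracy = 100 * mean(per_fold[, "accuracy"]),
    f1 = 100 * mean(per_fold[, "f1"], na.rm = TRUE),
    sensitivity = 100 * mean(per_fold[, "sensitivity"], na.rm = TRUE),
    specificity = 100 * mean(per_fold[, "specificity"], na.rm = TRUE),
    std_accuracy = 100 * stats::sd(per_fold[, "accuracy"])
  )
}

# ---- nested cross-validation -------------------------------------------

#' Nested cross-validation configuration
#'
#' @param normalization Normalization strategy name.
#' @param selector A [selector_config()].
#' @param classifiers Base classifier roster, a subset of
#'   `c("svm", "rf", "lr", "mlp", "xgb")`.
#' @param outer_folds,inner_folds Fold counts (10 and 5 by default).
#' @param seed Master seed; every random draw derives from it.
#' @param grids Named list of hyperparameter grids (defaults documented
#'   in [default_hyper_grids()]).
#' @param membership_threshold,escalation_threshold Ensemble thresholds
#'   (see [dynamic_ensemble()]).
#' @param selection_scope `"per_fold"` refits the selector inside each
#'   outer training fold (leakage-free); `"global"` selects once on the
#'   full matrix, mimicking pre-generated selection.
#' @param fit_scope Same switch for imputation/normalization statistics.
#' @return A `cv_config` list.
#' @export
cv_config <- function(normalization = "unnormalized",
                      selector = selector_config(),
                      classifiers = c("svm", "rf", "lr", "mlp", "xgb"),
                      outer_folds = 10L, inner_folds = 5L, seed = 1L,
                      grids = default_hyper_grids(),
                      membership_threshold = NULL,
                      escalation_threshold = 0,
                      selection_scope = c("per_fold", "global"),
                      fit_scope = c("per_fold", "global")) {
  stopifnot(all(classifiers %in% c("svm", "rf", "lr", "mlp", "xgb")),
            length(classifiers) >= 1L)
  structure(
    list(normalization = normalization, selector = selector,
         classifiers = classifiers, outer_folds = as.integer(outer_folds),
         inner_folds = as.integer(inner_folds), seed = as.integer(seed),
         grids = grids, membership_threshold = membership_threshold,
         escalation_threshold = escalation_threshold,
         selection_scope = match.arg(selection_scope),
         fit_scope = match.arg(fit_scope)),
    class = "cv_config"
  )
}

#' Run one nested cross-validated pipeline
#'
#' For each outer fold: imputation and normalization statistics are fit
#' on the training rows, the feature selector is refit on training rows,
#' each base classifier is tuned by inner stratified CV on the training
#' rows, refit on the full training fold, and evaluated on the held-out
#' fold; soft and hard dynamic voting ensembles are assembled from the
#' per-fold inner scores. Fully deterministic given the config seed.
#'
#' @param matrix A labelled `feature_matrix` (NAs allowed; imputed
#'   per fold).
#' @param config A [cv_config()].
#' @return A list of class `nested_cv_result`: `fold_results` tibble
#'   (per fold: selected features, members, per-model inner scores),
#'   `predictions` tibble (per model and row: fold, truth, prediction,
#'   patient probability), and `metrics` tibble (per model).
#' @export
run_nested_cv <- function(matrix, config = cv_config()) {
  y <- as_label_factor(matrix$label)
  if (anyNA(y)) stop("matrix must carry binary labels", call. = FALSE)
  n <- nrow(matrix)
  fold <- stratified_folds(y, config$outer_folds, seed = config$seed)
  model_names <- config$classifiers
  all_models <- c(model_names, "soft_ensemble", "hard_ensemble")

  global_sel <- NULL
  if (config$selection_scope == "global" || config$fit_scope == "global") {
    prep_all <- impute_missing(matrix)
    prep_all <- fit_apply_normalizer(prep_all, normalization_spec(config$normalization))$matrix
    if (config$selection_scope == "global") {
      global_sel <- select_features(feature_design(prep_all), y, config$selector,
                                    seed = config$seed)
    }
    if (config$fit_scope == "global") global_prep <- prep_all
  }

  fold_results <- list()
  pred_rows <- list()
  for (f in seq_len(config$outer_folds)) {
    train <- which(fold != f)
    test <- which(fold == f)
    if (length(unique(y[train])) < 2L) {
      stop("a training fold lost a class: stratification violated", call. = FALSE)
    }
    fold_seed <- config$seed + 7919L * f
    if (config$fit_scope == "global") {
      prep <- global_prep
    } else {
      prep <- impute_missing(matrix, reference_rows = train)
      prep <- fit_apply_normalizer(prep, normalization_spec(config$normalization),
                                   fit_rows = train)$matrix
    }
    X <- feature_design(prep)
    selected <- if (config$selection_scope == "global") {
      global_sel
    } else {
      select_features(X[train, , drop = FALSE], y[train], config$selector,
                      seed = fold_seed)
    }
    Xs <- X[, selected, drop = FALSE]

    fold_predictions <- list()
    inner_scores <- numeric(0)
    hyper <- list()
    for (m in seq_along(model_names)) {
      name <- model_names[m]
      # single-candidate grids are still inner-CV scored: the score gates
      # ensemble membership
      tune <- inner_cv_tune(name, Xs[train, , drop = FALSE], y[train],
                            config$grids[[name]], config$inner_folds,
                            seed = fold_seed + 13L * m)
      fit <- fit_base_model(name, Xs[train, , drop = FALSE], y[train],
                            tune$params, seed = fold_seed + 101L * m)
      fold_predictions[[name]] <- predict_base_model(fit, Xs[test, , drop = FALSE])
      inner_scores[name] <- tune$inner_score
      hyper[[name]] <- tune$params
    }
    ens <- dynamic_ensemble(fold_predictions, inner_scores,
                            membership_threshold = config$membership_threshold,
                            escalation_threshold = config$escalation_threshold)
    fold_predictions$soft_ensemble <- ens$soft
    fold_predictions$hard_ensemble <- ens$hard

    fold_results[[f]] <- tibble::tibble(
      fold = f,
      selected_features = list(selected),
      hyperparameters = list(hyper),
      inner_scores = list(inner_scores),
      ensemble_members = list(ens$members),
      membership_threshold = ens$threshold
    )
    pred_rows[[f]] <- purrr::map_dfr(all_models, function(name) {
      tibble::tibble(
        model = name, fold = f, row = test,
        truth = as.character(y[test]),
        prediction = as.character(fold_predictions[[name]]$label),
        prob_patient = fold_predictions[[name]]$prob[, "patient"]
      )
    })
  }

  predictions <- dplyr::bind_rows(pred_rows)
  metrics <- predictions |>
    dplyr::group_by(.data$model) |>
    dplyr::group_modify(~ compute_metrics(.x$prediction, .x$truth, .x$fold)) |>
    dplyr::ungroup()
  structure(
    list(fold_results = dplyr::bind_rows(fold_results),
         predictions = predictions, metrics = metrics, config = config),
    class = "nested_cv_result"
  )
}

# ---- sweeps -------------------------------------------------------------

#' Sweep configuration grid
#'
#' @param normalizations Normalization strategy names.
#' @param selectors Selector method names.
#' @param k_values Feature-count grid.
#' @param classifiers Model roster including ensembles; display names
#'   `"Soft Ensemble"`/`"Hard Ensemble"` or internal names are accepted.
#' @param seed Master seed.
#' @param lambda,step Selector hyperparameters passed through.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(normalizations = c("unnormalized", "minmax", "zscore"),
                         selectors = c("rf_importance", "xgb_weight", "l1", "rfe_rf"),
                         k_values = seq(100L, 150L, by = 5L),
                         classifiers = c("svm", "rf", "lr", "mlp", "xgb",
                                         "soft_ensemble", "hard_ensemble"),
                         seed = 1L, lambda = 0.05, step = 0.2) {
  stopifnot(length(k_values) >= 1L, length(classifiers) >= 1L)
  structure(list(normalizations = normalizations, selectors = selectors,
                 k_values = as.integer(k_values), classifiers = classifiers,
                 seed = as.integer(seed), lambda = lambda, step = step),
            class = "sweep_config")
}

#' Enumerate the configuration grid
#'
#' Cartesian product normalization x selector x k x classifier in stable
#' order (normalization-major).
#'
#' @param config A [sweep_config()].
#' @return Tibble with one row per configuration.
#' @export
enumerate_configurations <- function(config) {
  grid <- expand.grid(
    classifier = config$classifiers, k = config$k_values,
    selector = config$selectors, normalization = config$normalizations,
    stringsAsFactors = FALSE
  )
  tibble::as_tibble(grid[, c("normalization", "selector", "k", "classifier")]) |>
    dplyr::arrange(match(.data$normalization, config$normalizations),
                   match(.data$selector, config$selectors),
                   match(.data$k, config$k_values),
                   match(.data$classifier, config$classifiers))
}

display_classifier <- function(x) {
  map <- c(svm = "SVM", rf = "RF", lr = "LR", mlp = "MLP", xgb = "XGBoost",
           soft_ensemble = "Soft Ensemble", hard_ensemble = "Hard Ensemble")
  unname(map[x])
}

display_selector <- function(x) {
  map <- c(rf_importance = "RF Importance", xgb_weight = "XGB Importance",
           l1 = "L1 Regularization", rfe_rf = "RFE Random Forest")
  unname(map[x])
}

#' Run a full configuration sweep
#'
#' Executes [run_nested_cv()] once per (normalization, selector, k) cell
#' — the base models and both ensembles are fitted together — and emits
#' one metrics row per configuration, plus per-fold selected-feature
#' records for the frequency analyses.
#'
#' @param matrix A labelled `feature_matrix`.
#' @param config A [sweep_config()].
#' @param ... Passed to [cv_config()] (e.g. `outer_folds`, `grids`).
#' @return A list of class `sweep_result`: `table` (one row per
#'   configuration, sorted by accuracy) and `selections` (per
#'   normalization/selector/k/fold selected feature names).
#' @export
run_sweep <- function(matrix, config = sweep_config(), ...) {
  cells <- enumerate_configurations(config) |>
    dplyr::distinct(.data$normalization, .data$selector, .data$k)
  internal_classifiers <- intersect(config$classifiers,
                                    c("svm", "rf", "lr", "mlp", "xgb"))
  if (length(internal_classifiers) == 0L) {
    internal_classifiers <- c("svm", "rf", "lr", "mlp", "xgb")
  }
  rows <- list()
  selections <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sel <- selector_config(cell$selector, k = cell$k, lambda = config$lambda,
                           step = config$step)
    res <- run_nested_cv(matrix, cv_config(
      normalization = cell$normalization, selector = sel,
      classifiers = internal_classifiers, seed = config$seed, ...
    ))
    keep <- res$metrics |>
      dplyr::filter(.data$model %in% config$classifiers) |>
      dplyr::mutate(normalization = cell$normalization,
                    selector = cell$selector, k = cell$k)
    rows[[i]] <- keep
    selections[[i]] <- res$fold_results |>
      dplyr::transmute(normalization = cell$normalization,
                       selector = cell$selector, k = cell$k,
                       fold = .data$fold,
                       selected_features = .data$selected_features)
  }
  table <- dplyr::bind_rows(rows) |>
    dplyr::transmute(
      normalization = .data$normalization,
      classifier = display_classifier(.data$model),
      feature_selection = display_selector(.data$selector),
      k = .data$k,
      accuracy = .data$accuracy, f1 = .data$f1,
      sensitivity = .data$sensitivity, specificity = .data$specificity,
      std_accuracy = .data$std_accuracy
    ) |>
    dplyr::arrange(dplyr::desc(.data$accuracy))
  structure(list(table = table, selections = dplyr::bind_rows(selections),
                 config = config),
            class = "sweep_result")
}

#' Top-N table in the published column schema
#'
#' @param sweep A `sweep_result`.
#' @param n Number of rows.
#' @return Tibble with columns Classifier, Feature Selection, k,
#'   Accuracy (%), F1 Score (%), Sensitivity (%), Specificity (%),
#'   Std Accuracy.
#' @export
top_configurations <- function(sweep, n = 15L) {
  sweep$table |>
    dplyr::slice_head(n = n) |>
    dplyr::transmute(
      Classifier = .data$classifier,
      `Feature Selection` = .data$feature_selection,
      k = .data$k,
      `Accuracy (%)` = round(.data$accuracy, 2),
      `F1 Score (%)` = round(.data$f1, 2),
      `Sensitivity (%)` = round(.data$sensitivity, 2),
      `Specificity (%)` = round(.data$specificity, 2),
      `Std Accuracy` = round(.data$std_accuracy, 2)
    )
}
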