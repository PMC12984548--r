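# Planted-signal design: one informative column among noise.
planted_design <- function(seed, n = 120L, p = 20L, signal_cols = 1L,
                           effect = 2.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("F%02d", seq_len(p))
  y <- rep(c("healthy", "patient"), length.out = n)
  for (j in seq_len(signal_cols)) {
    X[y == "patient", j] <- X[y == "patient", j] + effect
  }
  list(X = X, y = factor(y, levels = c("healthy", "patient")))
}

test_that("forest importance recovers a planted signal and normalizes", {
  hits <- 0
  for (seed in 1:10) {
    d <- planted_design(seed)
    r <- rank_rf_importance(d$X, d$y, seed = seed)
    expect_equal(sum(r$score), 1, tolerance = 1e-9)
    if (r$feature[1] == "F01") hits <- hits + 1
  }
  expect_gte(hits, 9)
  d <- planted_design(1)
  expect_error(rank_rf_importance(d$X, rep("patient", nrow(d$X))), "constant")
})

test_that("boosted-tree split-count importance finds the signal, zeros unused", {
  top5 <- 0
  for (seed in 1:10) {
    d <- planted_design(seed)
    r <- rank_xgb_weight(d$X, d$y, seed = seed)
    expect_equal(sum(r$score), 1, tolerance = 1e-9)
    if ("F01" %in% r$feature[1:5]) top5 <- top5 + 1
    expect_true(any(r$score == 0) || all(r$score > 0))
  }
  expect_gte(top5, 9)
})

test_that("lasso ranking shrinks to zero and finds linear signal", {
  d <- planted_design(1)
  r_big <- rank_l1(d$X, d$y, lambda = 50)
  expect_true(all(r_big$score == 0))
  hits <- 0
  for (seed in 1:10) {
    d <- planted_design(seed)
    r <- rank_l1(d$X, d$y, lambda = 0.05)
    if (r$feature[1] == "F01") hits <- hits + 1
    expect_true(any(r$score == 0))
  }
  expect_gte(hits, 9)
})

test_that("recursive elimination returns exactly k features and recovers signal", {
  d <- planted_design(3, signal_cols = 3L)
  expect_equal(select_rfe(d$X, d$y, k = ncol(d$X), seed = 1),
               colnames(d$X))
  recovered <- vapply(1:10, function(seed) {
    d <- planted_design(seed, signal_cols = 3L)
    sel <- select_rfe(d$X, d$y, k = 3L, seed = seed)
    expect_length(sel, 3L)
    sum(c("F01", "F02", "F03") %in% sel)
  }, numeric(1))
  expect_gte(median(recovered), 2)
  expect_error(select_rfe(d$X, d$y, k = 50L), "exceeds")
})

test_that("top-k selection breaks ties by canonical order", {
  ranking <- make_ranking(sprintf("F%02d", 1:10), rep(1, 10))
  expect_equal(select_top_k(ranking, 3L), c("F01", "F02", "F03"))
  r2 <- make_ranking(c("A", "B", "C"), c(0.1, 0.9, 0.5))
  expect_equal(select_top_k(r2, 2L), c("B", "C"))
  expect_equal(select_top_k(r2, 3L), c("B", "C", "A"))
  expect_error(select_top_k(r2, 0L), "positive")
  expect_error(select_top_k(r2, 4L), "exceeds")
})

test_that("soft voting averages distributions and breaks exact ties to patient", {
  sv <- soft_vote(list(c(healthy = 0.6, patient = 0.4),
                       c(healthy = 0.8, patient = 0.2)))
  expect_equal(unname(sv$prob), c(0.7, 0.3))
  expect_equal(as.character(sv$label), "healthy")

  single <- soft_vote(list(c(healthy = 0.3, patient = 0.7)))
  expect_equal(unname(single$prob), c(0.3, 0.7))

  tie <- soft_vote(list(c(healthy = 0.6, patient = 0.4),
                        c(healthy = 0.4, patient = 0.6)))
  expect_equal(as.character(tie$label), "patient")

  expect_error(soft_vote(list(c(healthy = 0.5, patient = 0.4))), "sum to 1")
})

test_that("hard voting takes the majority with soft-probability tie-breaks", {
  expect_equal(as.character(hard_vote(c("patient", "patient", "healthy"))), "patient")
  expect_equal(as.character(hard_vote(rep("healthy", 3))), "healthy")
  tie <- hard_vote(c("patient", "healthy"),
                   list(c(healthy = 0.6, patient = 0.4),
                        c(healthy = 0.6, patient = 0.4)))
  expect_equal(as.character(tie), "healthy")
  tie2 <- hard_vote(c("patient", "healthy"),
                    list(c(healthy = 0.4, patient = 0.6),
                         c(healthy = 0.4, patient = 0.6)))
  expect_equal(as.character(tie2), "patient")
})

test_that("dynamic ensembles admit members by the inner-score threshold", {
  preds <- function(p) list(prob = cbind(healthy = 1 - p, patient = p),
                            label = factor(ifelse(p >= 0.5, "patient", "healthy"),
                                           levels = c("healthy", "patient")))
  fold_preds <- list(a = preds(c(0.9, 0.9)), b = preds(c(0.1, 0.2)),
                     c = preds(c(0.2, 0.1)))
  scores <- c(a = 0.9, b = 0.5, c = 0.55)
  ens <- dynamic_ensemble(fold_preds, scores)
  # threshold = mean(0.9, 0.5, 0.55) = 0.65: only model a qualifies
  expect_equal(ens$members, "a")
  expect_equal(as.character(ens$hard$label), c("patient", "patient"))

  # two weak members outvote one strong member under a permissive threshold
  ens2 <- dynamic_ensemble(fold_preds, scores, membership_threshold = 0)
  expect_equal(sort(ens2$members), c("a", "b", "c"))
  expect_equal(as.character(ens2$hard$label), c("healthy", "healthy"))

  # identical members leave the prediction unchanged
  same <- list(a = preds(c(0.8, 0.3)), b = preds(c(0.8, 0.3)))
  ens3 <- dynamic_ensemble(same, c(a = 0.7, b = 0.7))
  expect_equal(as.character(ens3$soft$label), c("patient", "healthy"))
  expect_equal(as.character(ens3$hard$label), c("patient", "healthy"))
})

test_that("metrics match hand-computed confusion arithmetic", {
  all_right <- compute_metrics(rep(c("patient", "healthy"), 5),
                               rep(c("patient", "healthy"), 5),
                               rep(1:2, each = 5))
  expect_equal(all_right$accuracy, 100)
  expect_equal(all_right$sensitivity, 100)
  expect_equal(all_right$std_accuracy, 0)

  # TP 9, FN 1, TN 8, FP 2 in one fold
  truth <- c(rep("patient", 10), rep("healthy", 10))
  pred <- c(rep("patient", 9), "healthy", rep("healthy", 8), rep("patient", 2))
  m <- compute_metrics(pred, truth, rep(1L, 20))
  expect_equal(m$accuracy, 85)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  f1_pos <- 2 * 9 / (2 * 9 + 2 + 1)
  f1_neg <- 2 * 8 / (2 * 8 + 1 + 2)
  expect_equal(m$f1, 100 * (f1_pos + f1_neg) / 2, tolerance = 1e-9)

  # a one-class fold drops out of the sens/spec means but not accuracy
  m2 <- compute_metrics(c("patient", "patient", "healthy", "patient"),
                        c("patient", "patient", "healthy", "healthy"),
                        c(1L, 1L, 2L, 2L))
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$accuracy, 75)
})

test_that("configuration enumeration is the stable Cartesian product", {
  full <- sweep_config()
  expect_equal(nrow(enumerate_configurations(full)), 924L)
  one_norm <- sweep_config(normalizations = "unnormalized")
  expect_equal(nrow(enumerate_configurations(one_norm)), 308L)
  toy <- sweep_config(normalizations = "unnormalized",
                      selectors = c("l1", "rf_importance"),
                      k_values = 5L, classifiers = c("rf", "svm", "lr"))
  grid <- enumerate_configurations(toy)
  expect_equal(nrow(grid), 6L)
  expect_equal(grid$classifier[1:3], c("rf", "svm", "lr"))
  empty <- sweep_config(normalizations = character(0))
  expect_equal(nrow(enumerate_configurations(empty)), 0L)
})

# Small separable cohort matrix for end-to-end CV tests.
toy_matrix <- function(seed = 1L, n = 40L, p = 12L, effect = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("healthy", "patient"), length.out = n)
  X[y == "patient", 1:2] <- X[y == "patient", 1:2] + effect
  cols <- as.vector(vapply(1L, function(t) matrix_column_name(t, feature_names()),
                           character(48)))[seq_len(p)]
  colnames(X) <- cols
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)), label = y),
    tibble::as_tibble(X)
  )
  class(out) <- c("feature_matrix", class(out))
  out
}

test_that("nested cross-validation is deterministic and leakage-free", {
  mat <- toy_matrix()
  cfg <- cv_config(selector = selector_config("rf_importance", k = 5L),
                   classifiers = "rf", outer_folds = 4L, inner_folds = 3L,
                   seed = 7L)
  res1 <- run_nested_cv(mat, cfg)
  res2 <- run_nested_cv(mat, cfg)
  expect_identical(res1$predictions, res2$predictions)
  expect_identical(res1$fold_results$selected_features,
                   res2$fold_results$selected_features)

  # outer test folds partition the cohort
  rows <- sort(res1$predictions$row[res1$predictions$model == "rf"])
  expect_equal(rows, seq_len(nrow(mat)))

  # perturbing rows outside a fold's training set does not change that
  # fold's selected features (fit statistics come from training rows only)
  fold1_test <- res1$predictions$row[res1$predictions$model == "rf" &
                                       res1$predictions$fold == 1L]
  mat2 <- mat
  mat2[fold1_test, matrix_column_name(1L, "TT")] <- 1e5
  res3 <- run_nested_cv(mat2, cfg)
  expect_identical(res1$fold_results$selected_features[[1]],
                   res3$fold_results$selected_features[[1]])

  # a separable design classifies well above chance
  acc <- res1$metrics$accuracy[res1$metrics$model == "hard_ensemble"]
  expect_gt(acc, 80)
})

test_that("sweeps emit one sorted metrics row per configuration", {
  mat <- toy_matrix()
  cfg <- sweep_config(normalizations = "zscore",
                      selectors = c("rf_importance", "l1"),
                      k_values = c(4L, 8L),
                      classifiers = c("rf", "hard_ensemble"))
  res <- run_sweep(mat, cfg, outer_folds = 3L, inner_folds = 2L,
                   grids = list(rf = data.frame(ntree = 100L)))
  expect_equal(nrow(res$table), 8L)
  expect_true(all(diff(res$table$accuracy) <= 0))
  expect_equal(unique(res$table$normalization), "zscore")

  top <- top_configurations(res, 3L)
  expect_equal(names(top),
               c("Classifier", "Feature Selection", "k", "Accuracy (%)",
                 "F1 Score (%)", "Sensitivity (%)", "Specificity (%)",
                 "Std Accuracy"))

  td <- tidy(res)
  expect_identical(td, res$table)
  gl <- glance(res)
  expect_equal(gl$n_configurations, 8L)
  expect_equal(gl$best_accuracy, max(res$table$accuracy))
})
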