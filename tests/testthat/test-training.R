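test_that("oversampling equalizes class counts by duplicating rows", {
  set.seed(4)
  x <- matrix(runif(18 * 3), 18)
  label <- rep(c(0L, 1L, 2L), times = c(10L, 3L, 5L))
  ft <- toy_feature_table(x, label)
  bal <- oversample_to_balance(ft, seed = 1)
  expect_identical(as.integer(table(bal$label)), rep(10L, 3L))
  expect_identical(length(bal$label), 30L)
  # every added row duplicates an existing same-class row
  for (i in 19:30) {
    cls <- bal$label[i]
    orig <- ft$x[ft$label == cls, , drop = FALSE]
    expect_true(any(apply(orig, 1, function(r) all(r == bal$x[i, ]))))
  }
  balanced <- toy_feature_table(x[1:9, ], rep(0:2, each = 3L))
  expect_identical(oversample_to_balance(balanced, seed = 1), balanced)
})

test_that("k-fold plans cover every sample exactly once", {
  labels <- rep(0:4, each = 20L)
  plan <- make_folds(labels, "kfold5", seed = 3)
  expect_identical(sort(unique(plan$assignment)), 1:5)
  expect_identical(as.integer(table(plan$assignment)), rep(20L, 5L))
  # stratification: each fold holds 4 of each class
  for (f in 1:5) {
    expect_identical(as.integer(table(labels[plan$assignment == f])),
                     rep(4L, 5L))
  }
  expect_identical(make_folds(labels, "kfold5", seed = 3)$assignment,
                   plan$assignment)
})

test_that("leave-two-subjects-out pairs subjects into disjoint folds", {
  subjects <- rep(sprintf("S%02d", 1:12), each = 10L)
  plan <- make_folds(rep(0L, length(subjects)), "leave_two_subjects_out",
                     subjects = subjects, seed = 7)
  expect_identical(plan$k, 6L)
  for (f in 1:6) {
    test_subj <- unique(subjects[plan$assignment == f])
    train_subj <- unique(subjects[plan$assignment != f])
    expect_length(test_subj, 2L)
    expect_length(train_subj, 10L)
    expect_length(intersect(test_subj, train_subj), 0L)
  }
  expect_error(make_folds(rep(0L, 5), "leave_two_subjects_out",
                          subjects = sprintf("S%d", 1:5)), "even")
})

test_that("Bayesian tuning spends exactly its budget and returns best-observed", {
  ft <- planted_feature_table(n = 40L, p_noise = 3L)
  res <- tune_hyperparameters("knn", ft, budget = 15, seed = 3)
  expect_identical(nrow(res$trace), 15L)
  expect_identical(res$objective, min(res$trace$objective))
  # best-observed contract: no evaluated configuration beats the winner
  expect_true(all(res$trace$objective >= res$objective))
  expect_error(tune_hyperparameters("knn", ft, budget = 0), ">= 1")

  res_dt <- tune_hyperparameters("decision_tree", ft, budget = 6, seed = 4)
  expect_identical(nrow(res_dt$trace), 6L)
  expect_true(all(c("minbucket", "split") %in% names(res_dt$hyperparameters)))
})

test_that("each classifier family trains and predicts integer scores", {
  set.seed(10)
  n <- 60L
  label <- rep(0:2, each = 20L)
  x <- matrix(runif(n * 5L), n)
  x[, 1L] <- label / 2 + rnorm(n, sd = 0.05)
  colnames(x) <- sprintf("f%d", 1:5)
  ft <- toy_feature_table(x, label)
  for (algo in algorithm_families()) {
    model <- train_model(model_spec(algo), ft)
    pred <- predict(model, ft)
    expect_true(all(pred %in% 0:4), label = algo)
    expect_gt(mean(pred == label), 0.5, label = algo)
  }

  # 1-NN memorizes its training data
  m1 <- train_model(model_spec("knn", hyperparameters = list(k = 1)), ft)
  expect_identical(predict(m1, ft), label)

  # linearly separated two-class toy: decision tree is perfect
  sep <- toy_feature_table(cbind(f = c(1:10 / 10, 2 + 1:10 / 10)),
                           rep(c(0L, 3L), each = 10L))
  mt <- train_model(model_spec("decision_tree"), sep)
  expect_identical(precision_recall_f1(sep$label, predict(mt, sep))$f1, 1)

  # single-class data yields a constant predictor for any family
  one <- toy_feature_table(matrix(runif(20), 10), rep(2L, 10L))
  for (algo in algorithm_families()) {
    expect_identical(predict(train_model(model_spec(algo), one), one),
                     rep(2L, 10L), label = algo)
  }

  expect_error(predict(m1, toy_feature_table(cbind(z = 1:3 / 3), 0:2)),
               "schema")
})

test_that("individual experiments pool each sample into test exactly once", {
  cfg <- small_cohort_config(n_subjects = 1L, recordings = 2L, seconds = 60,
                             rater_sd = 0.3, seed = 61)
  table <- cohort_tables(cfg)$tables$upper
  econf <- experiment_config(algorithms = "knn", settings = c("ALL", "SFS"),
                             seed = 5)
  exp <- run_individual_experiment(table, econf)
  expect_false(exp$skipped)
  for (v in exp$variants) {
    test_cover <- sort(unlist(lapply(v$folds, `[[`, "test_idx")))
    expect_identical(test_cover, seq_len(nrow(table$meta)))
    for (f in v$folds) {
      expect_length(intersect(f$train_idx, f$test_idx), 0L)
    }
  }

  one_class <- imudys:::subset_table(
    table, which(table$meta$median_score == table$meta$median_score[1]))
  skip_rec <- run_individual_experiment(one_class, econf)
  expect_true(skip_rec$skipped)
  expect_match(skip_rec$reason, "single label")
})

test_that("training artifacts are fitted on training partitions only", {
  cfg <- small_cohort_config(n_subjects = 4L, recordings = 1L, seconds = 40,
                             rater_sd = 0.3, seed = 62)
  table <- cohort_tables(cfg)$tables$upper
  econf <- experiment_config(algorithms = "decision_tree", settings = "ALL",
                             seed = 9)
  gen <- run_generalized_experiment(table, econf)
  features <- extract_feature_matrix(table)
  for (v in gen$variants) {
    for (f in v$folds) {
      # normalization provenance: params equal a fresh fit on the training
      # rows alone, untouched by the held-out rows
      refit <- fit_normalization(imudys:::subset_features(features,
                                                          f$train_idx))
      expect_equal(f$norm_params$min, refit$min, tolerance = 1e-12)
      expect_equal(f$norm_params$max, refit$max, tolerance = 1e-12)
      # grouping: no test subject contributes training rows
      expect_length(intersect(table$meta$subject_id[f$train_idx],
                              table$meta$subject_id[f$test_idx]), 0L)
    }
  }
})
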