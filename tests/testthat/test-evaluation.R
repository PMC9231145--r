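test_that("precision, recall and F1 match hand-computed contingency toys", {
  # class 1: TP=8, FP=2, FN=2
  true <- c(rep(1L, 10L), rep(0L, 10L))
  pred <- c(rep(1L, 8L), rep(0L, 2L), rep(0L, 8L), rep(1L, 2L))
  m <- precision_recall_f1(true, pred)
  c1 <- m$per_class[m$per_class$class == 1, ]
  expect_equal(c1$precision, 0.8)
  expect_equal(c1$recall, 0.8)
  expect_equal(c1$f1, 0.8)

  expect_identical(precision_recall_f1(0:4, 0:4)$f1, 1)

  # 3-class toy: each class has TP=1, FP=1, FN=1, so per-class F1 = 0.5
  m3 <- precision_recall_f1(c(0L, 0L, 1L, 1L, 2L, 2L),
                            c(0L, 1L, 1L, 2L, 2L, 0L))
  expect_equal(m3$per_class$f1, rep(0.5, 3))
  expect_equal(m3$f1, 0.5)

  # a class never predicted gets precision 0, kept in the macro mean
  mz <- precision_recall_f1(c(0L, 0L, 1L), c(0L, 0L, 0L))
  expect_identical(mz$per_class$precision[mz$per_class$class == 1], 0)

  expect_error(precision_recall_f1(0:1, 0L), "length")
})

test_that("RMSE treats scores as integers with known bounds", {
  expect_identical(rmse_scores(c(0L, 3L), c(0L, 3L)), 0)
  expect_identical(rmse_scores(c(0L, 1L, 2L), c(1L, 2L, 3L)), 1)
  expect_identical(rmse_scores(c(0L, 4L), c(4L, 0L)), 4)
  set.seed(2)
  for (i in 1:20) {
    t <- sample(0:4, 30, replace = TRUE)
    p <- sample(0:4, 30, replace = TRUE)
    expect_lte(rmse_scores(t, p), 4)
    expect_identical(rmse_scores(t, p) == 0, all(t == p))
  }
})

test_that("confusion matrices count on a fixed 0-4 axis", {
  cm <- score_confusion_matrix(c(0L, 1L, 1L), c(0L, 1L, 1L))
  expect_identical(unname(diag(cm)), c(1L, 2L, 0L, 0L, 0L))
  cm1 <- score_confusion_matrix(2L, 3L)
  expect_identical(unname(cm1[3L, 4L]), 1L)
  expect_identical(sum(cm1), 1L)
  set.seed(3)
  t <- sample(0:4, 50, replace = TRUE)
  p <- sample(0:4, 50, replace = TRUE)
  expect_identical(sum(score_confusion_matrix(t, p)), 50L)
  expect_error(score_confusion_matrix(c(0L, 5L), c(0L, 1L)), "0..4")
})

test_that("adjacent-error fraction summarizes near-miss structure", {
  cm <- matrix(0L, 5, 5)
  cm[1, 2] <- 3L; cm[1, 3] <- 1L
  expect_equal(adjacent_error_fraction(cm), 0.75)
  cm_adj <- matrix(0L, 5, 5); cm_adj[2, 1] <- 4L
  expect_identical(adjacent_error_fraction(cm_adj), 1)
  cm_far <- matrix(0L, 5, 5); cm_far[1, 3] <- 2L
  expect_identical(adjacent_error_fraction(cm_far), 0)
  perfect <- score_confusion_matrix(0:4, 0:4)
  expect_true(is.na(adjacent_error_fraction(perfect)))
})

test_that("macro F1 recomputed from the confusion matrix matches direct", {
  set.seed(4)
  for (i in 1:20) {
    t <- sample(0:3, 40, replace = TRUE)
    p <- pmin(4L, pmax(0L, t + sample(-1:1, 40, replace = TRUE)))
    direct <- precision_recall_f1(t, p)
    cm <- score_confusion_matrix(t, p)
    present <- sort(unique(t))
    f1_from_cm <- mean(vapply(present, function(c) {
      i <- c + 1L
      tp <- cm[i, i]; fp <- sum(cm[-i, i]); fn <- sum(cm[i, -i])
      pr <- if (tp + fp > 0) tp / (tp + fp) else 0
      rc <- if (tp + fn > 0) tp / (tp + fn) else 0
      if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    }, numeric(1)))
    expect_equal(direct$f1, f1_from_cm, tolerance = 1e-12)
    # permutation invariance
    perm <- sample(40)
    expect_equal(precision_recall_f1(t[perm], p[perm])$f1, direct$f1)
  }
})

test_that("label noise degrades expected macro F1 monotonically", {
  set.seed(5)
  true <- rep(0:4, each = 60L)
  f1_at <- vapply(c(0, 0.2, 0.4), function(noise) {
    mean(replicate(20, {
      flip <- runif(length(true)) < noise
      pred <- ifelse(flip, sample(0:4, length(true), replace = TRUE), true)
      precision_recall_f1(true, as.integer(pred))$f1
    }))
  }, numeric(1))
  expect_true(all(diff(f1_at) < 0))
})

test_that("best-model selection maximizes validation F1 with simplicity ties", {
  mk <- function(algo, setting, val, test) {
    list(algorithm = algo, setting = setting,
         validation = list(f1 = val),
         test = list(f1 = test, precision = test, recall = test))
  }
  single <- select_best_model(list(mk("knn", "ALL", 0.9, 0.8)))
  expect_identical(single$algorithm, "knn")

  two <- select_best_model(list(mk("knn", "ALL", 0.8, 0.9),
                                mk("svm", "SFS", 0.9, 0.5)))
  expect_identical(two$algorithm, "svm")

  tie <- select_best_model(list(mk("ensemble", "SFS+HYP", 0.9, 0.99),
                                mk("knn", "ALL", 0.9, 0.1)))
  expect_identical(tie$setting, "ALL")
})

test_that("experiment summaries average across subjects, skipping n/a", {
  rec <- function(v) list(validation_f1 = v, test_f1 = v,
                          test_precision = v, test_recall = v)
  same <- summarize_experiments(list(S1 = rec(0.7), S2 = rec(0.7)))
  expect_identical(same$sd_test_f1, 0)
  mix <- summarize_experiments(list(S1 = rec(0.5), S2 = rec(0.9), S3 = NULL))
  expect_identical(mix$n_subjects, 2L)
  expect_equal(mix$mean_test_f1, 0.7)
  expect_equal(mix$sd_test_f1, sd(c(0.5, 0.9)), tolerance = 1e-12)
})
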