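#' Build a cross-validation fold plan
#'
#' Two schemes:
#' \describe{
#'   \item{`kfold5`}{Sample-level k-fold (default k = 5; every iteration
#'     trains on 80% and tests on 20%, and each sample is tested exactly
#'     once).  Folds are stratified by label where class counts permit:
#'     samples are dealt round-robin over folds within a shuffled per-class
#'     order, which degrades gracefully to grouped-random assignment for
#'     classes smaller than k.}
#'   \item{`leave_two_subjects_out`}{Subject-level grouping: subjects are
#'     shuffled deterministically from the seed and paired into
#'     `n_subjects / 2` folds (6 folds for the canonical 12-subject
#'     cohort); a fold's two subjects never contribute training rows.}
#' }
#'
#' @param labels Integer labels (kfold5) used for stratification.
#' @param scheme `"kfold5"` or `"leave_two_subjects_out"`.
#' @param k Number of folds for `kfold5`.
#' @param subjects Character vector of per-sample subject ids
#'   (`leave_two_subjects_out` only).
#' @param seed Seed; identical inputs give an identical plan.
#' @return A `fold_plan`: `scheme`, integer `assignment` (per-sample fold
#'   id), `k`, and for LTSO the `fold_subjects` list.
#' @export
make_folds <- function(labels, scheme = c("kfold5", "leave_two_subjects_out"),
                       k = 5L, subjects = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "kfold5") {
    n <- length(labels)
    if (n < k) stop("need at least k samples for k-fold", call. = FALSE)
    assignment <- integer(n)
    with_seed(seed, {
      by_class <- split(seq_len(n), labels)
      order_all <- unlist(lapply(by_class, function(idx) {
        if (length(idx) > 1L) sample(idx) else idx
      }), use.names = FALSE)
      assignment[order_all] <- rep_len(seq_len(k), n)
    })
    structure(list(scheme = scheme, assignment = assignment, k = as.integer(k),
                   seed = as.integer(seed)), class = "fold_plan")
  } else {
    if (is.null(subjects)) stop("LTSO needs per-sample `subjects`",
                                call. = FALSE)
    uniq <- sort(unique(subjects))
    if (length(uniq) %% 2L != 0L) {
      stop("leave-two-subjects-out requires an even subject count",
           call. = FALSE)
    }
    n_folds <- length(uniq) %/% 2L
    shuffled <- with_seed(seed, sample(uniq))
    fold_subjects <- split(shuffled, rep(seq_len(n_folds), each = 2L))
    subj_fold <- stats::setNames(rep(seq_len(n_folds), each = 2L), shuffled)
    structure(list(scheme = scheme,
                   assignment = unname(subj_fold[subjects]),
                   k = n_folds,
                   fold_subjects = fold_subjects,
                   seed = as.integer(seed)), class = "fold_plan")
  }
}

#' Randomly oversample training rows to balance class counts
#'
#' Duplicates (with replacement) rows of every minority class until each
#' class present matches the majority count.  Applied to training
#' partitions only — test data is never resampled.
#'
#' @param features A `feature_table` (training partition).
#' @param seed Seed for the duplication draws.
#' @return The balanced `feature_table`; every added row is an exact
#'   duplicate of an existing same-class row.
#' @export
oversample_to_balance <- function(features, seed = 1L) {
  counts <- table(features$label)
  target <- max(counts)
  extra <- with_seed(seed, {
    unlist(lapply(names(counts), function(cls) {
      idx <- which(features$label == as.integer(cls))
      need <- target - length(idx)
      if (need > 0L) sample(idx, need, replace = TRUE) else integer(0)
    }), use.names = FALSE)
  })
  if (length(extra) == 0L) return(features)
  subset_features(features, c(seq_along(features$label), extra))
}

# One leakage-free fold evaluation: fit normalization and oversampling on
# the training rows only, train, predict the held-out rows.
fit_fold_and_predict <- function(algorithm, hyperparameters, selected,
                                 features, train_idx, test_idx, seed) {
  train_ft <- subset_features(features, train_idx)
  params <- fit_normalization(train_ft)
  train_n <- apply_normalization(train_ft, params)
  test_n <- apply_normalization(subset_features(features, test_idx), params)
  train_b <- oversample_to_balance(train_n, seed = seed)
  spec <- if (is.null(selected)) {
    model_spec(algorithm, "ALL", hyperparameters = hyperparameters)
  } else {
    model_spec(algorithm, "SFS", hyperparameters = hyperparameters,
               selected_features = selected)
  }
  model <- with_seed(seed, train_model(spec, train_b))
  list(predictions = with_seed(seed + 1L, predict(model, test_n)),
       norm_params = params)
}

# Pooled cross-validated predictions (the work-horse behind screening, SFS
# objectives, tuning objectives and validation metrics).
cv_pooled_predictions <- function(features, algorithm,
                                  hyperparameters = NULL, selected = NULL,
                                  k = 5L, seed = 1L) {
  plan <- make_folds(features$label, "kfold5",
                     k = min(k, length(features$label)), seed = seed)
  pred <- integer(length(features$label))
  for (f in seq_len(plan$k)) {
    test_idx <- which(plan$assignment == f)
    train_idx <- which(plan$assignment != f)
    res <- fit_fold_and_predict(algorithm, hyperparameters, selected,
                                features, train_idx, test_idx,
                                seed = substream_seed(seed, "cvfold", f))
    pred[test_idx] <- res$predictions
  }
  pred
}

# Inner-CV misclassification rate of one configuration.
cv_misclassification <- function(features, algorithm,
                                 hyperparameters = NULL, selected = NULL,
                                 k = 5L, seed = 1L) {
  pred <- cv_pooled_predictions(features, algorithm, hyperparameters,
                                selected, k = k, seed = seed)
  mean(pred != features$label)
}
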