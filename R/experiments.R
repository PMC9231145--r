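#' Experiment configuration
#'
#' Collects the training-protocol settings shared by the individual and
#' generalized experiments.  The defaults reproduce the study protocol:
#' 5-fold cross-validation, oversampled training partitions, SFS with a
#' budget of 20 objective evaluations, Bayesian hyperparameter tuning with
#' 15 evaluations during the first fold, and the 6 algorithm families x 4
#' settings grid.
#'
#' @param algorithms Algorithm families to run.
#' @param settings Model settings to run (subset of [model_settings()]).
#' @param k Outer/inner fold count for the sample-level CV.
#' @param sfs_budget SFS candidate-evaluation budget.
#' @param tune_budget Bayesian-optimization evaluation budget.
#' @param inner_folds Inner CV folds for validation / objectives.
#' @param feature_classes Feature-class names to extract.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(algorithms = algorithm_families(),
                              settings = model_settings(),
                              k = 5L, sfs_budget = 20L, tune_budget = 15L,
                              inner_folds = 5L,
                              feature_classes = imudys::feature_classes()$name,
                              sample_rate = 60, seed = 1L) {
  settings <- match.arg(settings, model_settings(), several.ok = TRUE)
  algorithms <- match.arg(algorithms, algorithm_families(), several.ok = TRUE)
  list(algorithms = algorithms, settings = settings, k = as.integer(k),
       sfs_budget = as.integer(sfs_budget),
       tune_budget = as.integer(tune_budget),
       inner_folds = as.integer(inner_folds),
       feature_classes = feature_classes,
       sample_rate = sample_rate, seed = as.integer(seed))
}

# Shared outer-CV engine for both experiment types.
#
# `assignment` is the per-sample outer fold id.  Per the first-fold
# protocol, SFS feature lists and tuned hyperparameters are computed once
# on fold 1's training partition and reused in all folds.  Validation
# predictions are pooled inner-CV predictions on each outer training
# partition; test predictions are pooled over the outer folds.
run_cv_grid <- function(features, assignment, config) {
  n_folds <- max(assignment)
  fold1_train <- which(assignment != 1L)
  fold1_ft <- subset_features(features, fold1_train)
  algorithms <- config$algorithms
  settings <- config$settings
  need_sfs <- any(startsWith(settings, "SFS"))
  need_hyp <- any(endsWith(settings, "HYP"))
  sfs_by_algo <- list()
  if (need_sfs) {
    for (algo in algorithms) {
      res <- sequential_forward_selection(
        fold1_ft, algo, max_evaluations = config$sfs_budget,
        inner_folds = config$inner_folds,
        seed = substream_seed(config$seed, "sfs", algo))
      # an empty selection cannot parameterize a model; fall back to the
      # full feature set for that family
      sfs_by_algo[[algo]] <- list(
        selected = if (length(res$selected)) res$selected else
          colnames(features$x),
        result = res)
    }
  }
  variants <- list()
  for (algo in algorithms) {
    for (setting in settings) {
      selected <- if (startsWith(setting, "SFS")) {
        sfs_by_algo[[algo]]$selected
      } else NULL
      hyper <- NULL
      tuning <- NULL
      if (endsWith(setting, "HYP")) {
        tuning <- tune_hyperparameters(
          algo, fold1_ft, selected = selected,
          budget = config$tune_budget, inner_folds = config$inner_folds,
          seed = substream_seed(config$seed, "tune", algo, setting))
        hyper <- tuning$hyperparameters
      }
      val_true <- integer(0)
      val_pred <- integer(0)
      test_pred <- integer(length(features$label))
      fold_provenance <- vector("list", n_folds)
      for (f in seq_len(n_folds)) {
        train_idx <- which(assignment != f)
        test_idx <- which(assignment == f)
        train_ft <- subset_features(features, train_idx)
        vp <- cv_pooled_predictions(
          train_ft, algo, hyperparameters = hyper, selected = selected,
          k = config$inner_folds,
          seed = substream_seed(config$seed, "val", algo, setting, f))
        val_true <- c(val_true, train_ft$label)
        val_pred <- c(val_pred, vp)
        res <- fit_fold_and_predict(
          algo, hyper, selected, features, train_idx, test_idx,
          seed = substream_seed(config$seed, "test", algo, setting, f))
        test_pred[test_idx] <- res$predictions
        fold_provenance[[f]] <- list(train_idx = train_idx,
                                     test_idx = test_idx,
                                     norm_params = res$norm_params)
      }
      variants[[paste(algo, setting, sep = "/")]] <- list(
        algorithm = algo, setting = setting,
        hyperparameters = hyper, tuning = tuning,
        selected_features = selected,
        sfs = if (startsWith(setting, "SFS")) sfs_by_algo[[algo]]$result,
        validation = evaluation_report(val_true, val_pred),
        test = evaluation_report(features$label, test_pred),
        test_predictions = test_pred,
        folds = fold_provenance)
    }
  }
  variants
}

#' Train and evaluate the model grid on one subject's data
#'
#' The individual-model experiment: the subject's own labelled windows are
#' split by stratified 5-fold cross-validation (80% train/validate, 20%
#' test per fold, every sample tested exactly once); per fold the training
#' partition is normalized, oversampled and fitted; SFS feature lists and
#' tuned hyperparameters come from fold 1's training partition and are
#' reused across folds; pooled test predictions are scored per variant.
#'
#' @param table The subject's `extremity_table`.
#' @param config An [experiment_config()].
#' @return A `dys_experiment` (or a skip record, when the subject's labels
#'   have fewer than two classes or too few samples): `variants`,
#'   `best` ([select_best_model()] winner), `fold_plan`, `features`.
#' @export
run_individual_experiment <- function(table, config = experiment_config()) {
  labels <- table$meta$median_score
  if (length(unique(labels)) < 2L) {
    return(structure(list(skipped = TRUE,
                          reason = "single label class",
                          n_samples = length(labels)),
                     class = "dys_experiment"))
  }
  if (length(labels) < config$k) {
    return(structure(list(skipped = TRUE, reason = "too few samples",
                          n_samples = length(labels)),
                     class = "dys_experiment"))
  }
  features <- extract_feature_matrix(table, classes = config$feature_classes,
                                     sample_rate = config$sample_rate)
  plan <- make_folds(features$label, "kfold5", k = config$k,
                     seed = substream_seed(config$seed, "outer",
                                           table$meta$subject_id[1]))
  variants <- run_cv_grid(features, plan$assignment, config)
  structure(list(skipped = FALSE,
                 scheme = "kfold5",
                 subject_id = table$meta$subject_id[1],
                 extremity = table$extremity,
                 n_samples = length(labels),
                 fold_plan = plan,
                 variants = variants,
                 best = select_best_model(variants)),
            class = "dys_experiment")
}

#' Train and evaluate the generalized model grid across subjects
#'
#' Leave-two-subjects-out cross-validation: subjects are paired into
#' folds (6 folds for 12 subjects); in each fold the remaining subjects'
#' pooled data is used for training and validation (inner 5-fold CV) and
#' the two left-out subjects form the test set, so no test subject ever
#' contributes training rows in its fold.  Test predictions are pooled
#' over the outer folds and scored with F1, RMSE and the confusion matrix.
#'
#' @param table Pooled `extremity_table` over all subjects.
#' @param config An [experiment_config()].
#' @return A `dys_experiment` with `variants`, `best` and the LTSO
#'   `fold_plan`.
#' @export
run_generalized_experiment <- function(table, config = experiment_config()) {
  subjects <- table$meta$subject_id
  if (length(unique(subjects)) < 4L) {
    stop("generalized experiment needs at least 4 subjects", call. = FALSE)
  }
  features <- extract_feature_matrix(table, classes = config$feature_classes,
                                     sample_rate = config$sample_rate)
  plan <- make_folds(features$label, "leave_two_subjects_out",
                     subjects = subjects,
                     seed = substream_seed(config$seed, "ltso"))
  variants <- run_cv_grid(features, plan$assignment, config)
  structure(list(skipped = FALSE,
                 scheme = "leave_two_subjects_out",
                 extremity = table$extremity,
                 n_samples = length(subjects),
                 fold_plan = plan,
                 variants = variants,
                 best = select_best_model(variants)),
            class = "dys_experiment")
}

#' @export
print.dys_experiment <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat(sprintf("<dys_experiment> skipped (%s), n=%d\n", x$reason,
                x$n_samples))
    return(invisible(x))
  }
  cat(sprintf("<dys_experiment> %s, %d variants, n=%d\n", x$scheme,
              length(x$variants), x$n_samples))
  print(x$best)
  invisible(x)
}

#' @export
summary.dys_experiment <- function(object, ...) {
  if (isTRUE(object$skipped)) {
    return(data.frame(skipped = TRUE, reason = object$reason))
  }
  out <- do.call(rbind, lapply(object$variants, function(v) {
    data.frame(algorithm = v$algorithm, setting = v$setting,
               validation_f1 = v$validation$f1,
               test_f1 = v$test$f1,
               test_precision = v$test$precision,
               test_recall = v$test$recall,
               test_rmse = v$test$rmse,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(-out$validation_f1), ]
}
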