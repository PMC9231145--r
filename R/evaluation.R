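#' Per-class and macro precision, recall and F1
#'
#' One-vs-rest per class `c`: `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`.
#' A class never predicted (TP + FP = 0) gets precision 0, and analogously
#' recall; such zeros stay in the macro mean.  The macro aggregate is the
#' unweighted mean over the classes present in `true` — the multi-class
#' averaging convention used throughout the package (reported in every
#' result object).
#'
#' @param true,predicted Equal-length integer label vectors over 0--4.
#' @return List with `per_class` (data frame: class, precision, recall, f1,
#'   support) and macro `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(true, predicted) {
  check_labels(true, predicted)
  classes <- sort(unique(true))
  per <- lapply(classes, function(c) {
    tp <- sum(true == c & predicted == c)
    fp <- sum(true != c & predicted == c)
    fn <- sum(true == c & predicted != c)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    data.frame(class = c, precision = precision, recall = recall, f1 = f1,
               support = tp + fn)
  })
  per <- do.call(rbind, per)
  list(per_class = per,
       precision = mean(per$precision),
       recall = mean(per$recall),
       f1 = mean(per$f1),
       averaging = "macro")
}

#' Root-mean-square error between true and predicted scores
#'
#' Treats the ordinal 0--4 labels as integers: `sqrt(mean((true - pred)^2))`.
#' Bounded by 4 on this scale; 0 iff the predictions are perfect.
#'
#' @param true,predicted Equal-length integer label vectors over 0--4.
#' @return Non-negative RMSE in score units.
#' @export
rmse_scores <- function(true, predicted) {
  check_labels(true, predicted)
  sqrt(mean((as.numeric(true) - as.numeric(predicted))^2))
}

#' 5x5 confusion matrix over the 0--4 score scale
#'
#' Entry (i, j) counts samples with true score i predicted as j; the class
#' axis is fixed at 0--4 even for absent classes.
#'
#' @param true,predicted Equal-length integer label vectors over 0--4.
#' @return 5x5 integer matrix with dimnames true x predicted.
#' @export
score_confusion_matrix <- function(true, predicted) {
  check_labels(true, predicted)
  table(factor(true, levels = 0:4), factor(predicted, levels = 0:4),
        dnn = c("true", "predicted"))
}

#' Fraction of misclassifications landing on an adjacent score
#'
#' Of all off-diagonal confusion counts, the share with |true - predicted|
#' equal to 1.  High values reproduce the clinical observation that most
#' errors confuse neighbouring severity levels.  Undefined (NA) when there
#' are no misclassifications.
#'
#' @param cm A 5x5 confusion matrix from [score_confusion_matrix()].
#' @return Fraction in [0, 1], or `NA` if the matrix is diagonal.
#' @export
adjacent_error_fraction <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(all(dim(cm) == c(5L, 5L)))
  d <- abs(row(cm) - col(cm))
  off <- sum(cm[d > 0])
  if (off == 0) return(NA_real_)
  sum(cm[d == 1]) / off
}

check_labels <- function(true, predicted) {
  if (length(true) != length(predicted)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(true) == 0L) stop("empty label vectors", call. = FALSE)
  if (any(!c(true, predicted) %in% 0:4)) {
    stop("labels must be integers in 0..4", call. = FALSE)
  }
  invisible(TRUE)
}

#' Full evaluation report for one model on one data split
#'
#' @param true,predicted Equal-length integer label vectors over 0--4.
#' @return An `evaluation_report`: per-class and macro precision / recall /
#'   F1, RMSE, 5x5 confusion matrix, adjacent-error fraction and sample
#'   count.
#' @export
evaluation_report <- function(true, predicted) {
  prf <- precision_recall_f1(true, predicted)
  cm <- score_confusion_matrix(true, predicted)
  structure(list(
    per_class = prf$per_class,
    precision = prf$precision,
    recall = prf$recall,
    f1 = prf$f1,
    averaging = prf$averaging,
    rmse = rmse_scores(true, predicted),
    confusion = cm,
    adjacent_error_fraction = adjacent_error_fraction(cm),
    n_samples = length(true)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n=%d  macro F1=%.3f  precision=%.3f  recall=%.3f  RMSE=%.3f\n",
    x$n_samples, x$f1, x$precision, x$recall, x$rmse))
  invisible(x)
}

#' Select the best model variant by validation F1
#'
#' Argmax of validation macro F1 among the trained variants.  Exact ties
#' are broken by the simpler setting first (`ALL < SFS < ALL+HYP <
#' SFS+HYP`), then by algorithm order in [algorithm_families()] — never by
#' test performance, which would leak the held-out data into selection.
#'
#' @param reports List of per-variant results, each with `algorithm`,
#'   `setting`, `validation` and `test` evaluation reports.
#' @return The winning variant record (a `best_model_record`).
#' @export
select_best_model <- function(reports) {
  if (length(reports) == 0L) stop("no variant reports", call. = FALSE)
  val_f1 <- vapply(reports, function(r) r$validation$f1, numeric(1))
  setting_rank <- match(vapply(reports, `[[`, character(1), "setting"),
                        model_settings())
  algo_rank <- match(vapply(reports, `[[`, character(1), "algorithm"),
                     algorithm_families())
  o <- order(-val_f1, setting_rank, algo_rank)
  win <- reports[[o[1L]]]
  structure(list(
    algorithm = win$algorithm,
    setting = win$setting,
    validation_f1 = win$validation$f1,
    test_f1 = win$test$f1,
    test_precision = win$test$precision,
    test_recall = win$test$recall,
    variant = win
  ), class = "best_model_record")
}

#' @export
print.best_model_record <- function(x, ...) {
  cat(sprintf("<best_model_record> %s / %s: validation F1=%.3f, test F1=%.3f\n",
              x$algorithm, x$setting, x$validation_f1, x$test_f1))
  invisible(x)
}

#' Summarize best-model records across subjects
#'
#' Unweighted mean and sample SD of validation / test F1, test precision
#' and test recall over the per-subject winners; subjects skipped for lack
#' of label variation are excluded.
#'
#' @param best_records Named list of `best_model_record`s (or `NULL` for
#'   skipped subjects).
#' @return One-row data frame of means and SDs plus the subject count.
#' @export
summarize_experiments <- function(best_records) {
  recs <- Filter(Negate(is.null), best_records)
  if (length(recs) == 0L) stop("no records to summarize", call. = FALSE)
  grab <- function(f) vapply(recs, `[[`, numeric(1), f)
  vals <- list(validation_f1 = grab("validation_f1"),
               test_f1 = grab("test_f1"),
               test_precision = grab("test_precision"),
               test_recall = grab("test_recall"))
  out <- data.frame(n_subjects = length(recs))
  for (nm in names(vals)) {
    out[[paste0("mean_", nm)]] <- mean(vals[[nm]])
    out[[paste0("sd_", nm)]] <- stats::sd(vals[[nm]])
  }
  out
}
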