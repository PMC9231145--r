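#' Screen feature classes by single-class predictive power
#'
#' For each candidate feature class, builds the 11-column feature table
#' (one feature class x 11 signals), trains every algorithm family at
#' default hyperparameters under cross-validation, and records the best
#' pooled validation macro F1.  A class passes if that best F1 reaches the
#' threshold (default 0.7).
#'
#' @param table An `extremity_table`.
#' @param candidate_classes Feature-class names to screen.
#' @param algorithms Algorithm families to try (default all six).
#' @param threshold Pass threshold on the best F1.
#' @param cv_folds Cross-validation folds.
#' @param seed Seed.
#' @param sample_rate Sampling rate, Hz.
#' @return A `screening_result` data frame: class, best F1, best algorithm,
#'   pass flag.
#' @export
screen_feature_classes <- function(table,
                                   candidate_classes = feature_classes()$name,
                                   algorithms = algorithm_families(),
                                   threshold = 0.7, cv_folds = 5L, seed = 1L,
                                   sample_rate = 60) {
  labels <- table$meta$median_score
  if (length(unique(labels)) < 2L) {
    stop("screening requires at least two label classes", call. = FALSE)
  }
  rows <- lapply(candidate_classes, function(cl) {
    ft <- extract_feature_matrix(table, classes = cl,
                                 sample_rate = sample_rate)
    f1s <- vapply(algorithms, function(algo) {
      pred <- cv_pooled_predictions(ft, algo, k = cv_folds,
                                    seed = substream_seed(seed, "screen", cl,
                                                          algo))
      precision_recall_f1(ft$label, pred)$f1
    }, numeric(1))
    data.frame(class = cl, best_f1 = max(f1s),
               best_algorithm = algorithms[which.max(f1s)],
               pass = max(f1s) >= threshold, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("screening_result", "data.frame"))
}

#' Sequential forward feature selection
#'
#' Greedy wrapper search from the empty candidate set: at each round every
#' remaining feature column is scored by the inner-cross-validated
#' misclassification rate of the learner trained on the current selection
#' plus that column, each such scoring consuming one unit of the
#' evaluation budget (default 20).  The best candidate is accepted iff it
#' strictly decreases the objective; the search stops when no candidate
#' improves or the budget is exhausted.  Objective ties are broken toward
#' the lower column index.  Deterministic given the seed.
#'
#' The starting objective is the misclassification rate of the
#' majority-class predictor, so the first feature must beat label
#' frequency alone to be accepted.
#'
#' @param features A `feature_table`.
#' @param algorithm Learner family used inside the wrapper (the same family
#'   that will be trained downstream).
#' @param hyperparameters Optional hyperparameters for the wrapper learner.
#' @param max_evaluations Total candidate-evaluation budget (>= 1).
#' @param inner_folds Inner CV folds for the objective.
#' @param seed Seed.
#' @return An `sfs_result`: `selected` (ordered column names), `trace`
#'   (objective after each accepted addition, non-increasing) and
#'   `evaluations_used`.
#' @export
sequential_forward_selection <- function(features, algorithm,
                                         hyperparameters = NULL,
                                         max_evaluations = 20L,
                                         inner_folds = 5L, seed = 1L) {
  if (!is.numeric(max_evaluations) || max_evaluations < 1L) {
    stop("`max_evaluations` must be >= 1", call. = FALSE)
  }
  if (ncol(features$x) < 1L) stop("no feature columns", call. = FALSE)
  if (length(unique(features$label)) < 2L) {
    stop("need at least two label classes", call. = FALSE)
  }
  columns <- colnames(features$x)
  selected <- character(0)
  remaining <- columns
  counts <- table(features$label)
  objective <- 1 - max(counts) / sum(counts)  # majority-class baseline
  trace <- numeric(0)
  used <- 0L
  repeat {
    if (length(remaining) == 0L || used >= max_evaluations) break
    best_obj <- Inf
    best_col <- NA_character_
    for (col in remaining) {  # column order fixes tie-breaks
      if (used >= max_evaluations) break
      obj <- cv_misclassification(
        features, algorithm, hyperparameters = hyperparameters,
        selected = c(selected, col), k = inner_folds,
        seed = substream_seed(seed, "sfs", length(selected)))
      used <- used + 1L
      if (obj < best_obj) {
        best_obj <- obj
        best_col <- col
      }
    }
    if (is.na(best_col) || best_obj >= objective) break
    selected <- c(selected, best_col)
    remaining <- setdiff(remaining, best_col)
    objective <- best_obj
    trace <- c(trace, best_obj)
  }
  structure(list(selected = selected, trace = trace,
                 evaluations_used = used),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("<sfs_result> %d features selected in %d evaluations\n",
              length(x$selected), x$evaluations_used))
  if (length(x$selected)) {
    cat("  ", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}
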