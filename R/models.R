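#' Specify a model variant
#'
#' An algorithm family plus one of the four settings (all features vs
#' SFS-selected features, with or without hyperparameter tuning), an
#' optional hyperparameter map and the selected feature columns for the
#' SFS settings.
#'
#' @param algorithm One of [algorithm_families()].
#' @param setting One of [model_settings()].
#' @param hyperparameters Named list of hyperparameters (`NULL` = family
#'   defaults).
#' @param selected_features Character vector of feature columns (required
#'   for the SFS settings).
#' @return A `model_spec`.
#' @export
model_spec <- function(algorithm, setting = "ALL", hyperparameters = NULL,
                       selected_features = NULL) {
  algorithm <- match.arg(algorithm, algorithm_families())
  setting <- match.arg(setting, model_settings())
  if (startsWith(setting, "SFS") && is.null(selected_features)) {
    stop("SFS settings require `selected_features`", call. = FALSE)
  }
  structure(list(algorithm = algorithm, setting = setting,
                 hyperparameters = hyperparameters,
                 selected_features = selected_features),
            class = "model_spec")
}

# Family-default hyperparameters (knn uses k = 5).
default_hyperparameters <- function(algorithm) {
  switch(algorithm,
    decision_tree = list(minbucket = 7, split = "gini"),
    discriminant = list(type = "linear"),
    naive_bayes = list(eps = 1e-9, threshold = 1e-3),
    svm = list(cost = 1, gamma = NA),  # NA gamma -> 1/p at fit time
    knn = list(k = 5),
    ensemble = list(ntree = 100, mtry = NA),
    stop("unknown algorithm: ", algorithm, call. = FALSE))
}

# Hyperparameter search space for sequential model-based optimization.
# Ranges follow standard practice for each family, bounded by the training
# size n and feature count p.
hp_space <- function(algorithm, n, p) {
  switch(algorithm,
    decision_tree = list(
      list(name = "minbucket", type = "int_log", lower = 1,
           upper = max(2, floor(n / 4))),
      list(name = "split", type = "cat", values = c("gini", "information"))),
    discriminant = list(
      list(name = "type", type = "cat", values = c("linear", "quadratic"))),
    naive_bayes = list(
      list(name = "eps", type = "num_log", lower = 1e-9, upper = 1e-1),
      list(name = "threshold", type = "num_log", lower = 1e-4, upper = 1e-1)),
    svm = list(
      list(name = "cost", type = "num_log", lower = 1e-3, upper = 1e3),
      list(name = "gamma", type = "num_log", lower = 1e-3, upper = 1e3)),
    knn = list(
      list(name = "k", type = "int_log", lower = 1,
           upper = max(2, min(30, floor(n / 2))))),
    ensemble = list(
      list(name = "ntree", type = "int_log", lower = 10, upper = 200),
      list(name = "mtry", type = "int_log", lower = 1, upper = max(1, p))),
    stop("unknown algorithm: ", algorithm, call. = FALSE))
}

#' Train one classifier
#'
#' Fits the requested family on a (normalized, oversampled) training
#' feature table.  For the SFS settings the columns are restricted to
#' `spec$selected_features` first.  Degenerate cases are total: a
#' single-class training set yields a constant predictor, and families
#' whose fit fails on a pathological fold (e.g. quadratic discriminant
#' with a class smaller than the feature count) fall back to linear
#' discriminant and finally to the majority class.
#'
#' @param spec A [model_spec()].
#' @param training A normalized `feature_table` (training partition).
#' @return A `dys_model` with a [predict][predict.dys_model] method mapping
#'   feature rows to integer scores 0--4.
#' @export
train_model <- function(spec, training) {
  x <- training$x
  if (!is.null(spec$selected_features)) {
    missing_cols <- setdiff(spec$selected_features, colnames(x))
    if (length(missing_cols)) {
      stop("selected features absent from table: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    x <- x[, spec$selected_features, drop = FALSE]
  }
  y <- factor(training$label, levels = 0:4)
  hp <- utils::modifyList(default_hyperparameters(spec$algorithm),
                          spec$hyperparameters %||% list())
  present <- levels(droplevels(y))
  fit <- if (length(present) < 2L) {
    list(kind = "constant", class = as.integer(present[1L]))
  } else {
    fit_family(spec$algorithm, x, droplevels(y), hp)
  }
  structure(list(spec = spec, fit = fit, columns = colnames(x),
                 hyperparameters = hp),
            class = "dys_model")
}

# Dispatch on family; always returns list(kind=..., ...).
fit_family <- function(algorithm, x, y, hp) {
  majority <- list(kind = "constant",
                   class = as.integer(names(which.max(table(y)))))
  switch(algorithm,
    knn = list(kind = "knn", x = x, y = y, k = hp$k),
    decision_tree = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      fit <- rpart::rpart(
        .y ~ ., data = df, method = "class",
        parms = list(split = hp$split),
        control = rpart::rpart.control(minbucket = hp$minbucket,
                                       minsplit = 2 * hp$minbucket,
                                       cp = 0.001, xval = 0))
      list(kind = "rpart", fit = fit)
    },
    discriminant = {
      keep <- keep_variable_columns(x)
      xk <- x[, keep, drop = FALSE]
      fit <- NULL
      if (identical(hp$type, "quadratic")) {
        fit <- tryCatch(MASS::qda(xk, y), error = function(e) NULL)
      }
      if (is.null(fit)) {
        fit <- tryCatch(suppressWarnings(MASS::lda(xk, y)),
                        error = function(e) NULL)
      }
      if (is.null(fit)) majority else
        list(kind = "da", fit = fit, keep = keep)
    },
    naive_bayes = {
      keep <- keep_variable_columns(x)
      fit <- tryCatch(
        e1071::naiveBayes(x[, keep, drop = FALSE], y),
        error = function(e) NULL)
      if (is.null(fit)) majority else
        list(kind = "nb", fit = fit, keep = keep, eps = hp$eps,
             threshold = hp$threshold)
    },
    svm = {
      gamma <- if (is.na(hp$gamma)) 1 / ncol(x) else hp$gamma
      fit <- tryCatch(
        e1071::svm(x, y, kernel = "radial", cost = hp$cost, gamma = gamma,
                   scale = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) majority else list(kind = "svm", fit = fit)
    },
    ensemble = {
      mtry <- if (is.na(hp$mtry)) max(1, floor(sqrt(ncol(x)))) else
        min(hp$mtry, ncol(x))
      fit <- randomForest::randomForest(x, y, ntree = hp$ntree, mtry = mtry)
      list(kind = "rf", fit = fit)
    },
    stop("unknown algorithm: ", algorithm, call. = FALSE))
}

# Columns with non-zero variance (density-based families need them).
keep_variable_columns <- function(x) {
  v <- apply(x, 2L, function(col) max(col) - min(col))
  keep <- which(v > 0)
  if (length(keep) == 0L) keep <- 1L
  keep
}

#' @export
print.dys_model <- function(x, ...) {
  cat(sprintf("<dys_model> %s (%s), %d features\n", x$spec$algorithm,
              x$spec$setting, length(x$columns)))
  invisible(x)
}

#' Predict integer severity scores
#'
#' @param object A `dys_model`.
#' @param newdata A `feature_table` (normalized with the training-fold
#'   parameters) or a feature matrix with matching column names.
#' @param ... Unused.
#' @return Integer vector of predicted scores 0--4.
#' @export
predict.dys_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_table")) newdata$x else as.matrix(newdata)
  missing_cols <- setdiff(object$columns, colnames(x))
  if (length(missing_cols)) {
    stop("prediction schema mismatch; missing columns: ",
         paste(utils::head(missing_cols, 3), collapse = ", "), call. = FALSE)
  }
  x <- x[, object$columns, drop = FALSE]
  fit <- object$fit
  pred <- switch(fit$kind,
    constant = rep(fit$class, nrow(x)),
    knn = as.integer(as.character(
      class::knn(fit$x, x, fit$y, k = min(fit$k, nrow(fit$x))))),
    rpart = as.integer(as.character(
      predict(fit$fit, data.frame(x, check.names = FALSE), type = "class"))),
    da = as.integer(as.character(
      predict(fit$fit, x[, fit$keep, drop = FALSE])$class)),
    nb = as.integer(as.character(
      predict(fit$fit, x[, fit$keep, drop = FALSE], type = "class",
              threshold = fit$threshold, eps = fit$eps))),
    svm = as.integer(as.character(predict(fit$fit, x))),
    rf = as.integer(as.character(predict(fit$fit, x))),
    stop("corrupt model object"))
  pred
}
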