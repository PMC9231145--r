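#' The default feature-class catalogue
#'
#' The ten time- and frequency-domain feature classes extracted per signal
#' per window after the screening round: absolute harmonic mean, absolute
#' maximum, bandpower, geometric mean, maximum, median, minimum,
#' root-mean-square, root-sum-of-squares and Shannon entropy.  With the 11
#' per-sensor signals this yields the 110-dimensional feature vector per
#' sample.
#'
#' @return Data frame with columns `name` and `domain` (time / frequency).
#' @export
feature_classes <- function() {
  data.frame(
    name = c("abs_harmonic_mean", "abs_maximum", "bandpower",
             "geometric_mean", "maximum", "median", "minimum",
             "rms", "rss", "shannon_entropy"),
    domain = c("time", "time", "frequency", "time", "time", "time", "time",
               "time", "time", "time"),
    stringsAsFactors = FALSE
  )
}

# Numerical floor used inside log/reciprocal feature definitions, channel
# units.  Makes every feature class total on arbitrary finite signals.
.feature_eps <- 1e-12

#' Extract one feature from one windowed signal
#'
#' Definitions over the n samples `s` of a window:
#' \itemize{
#'   \item `abs_harmonic_mean`: `n / sum(1 / pmax(|s|, eps))`
#'   \item `abs_maximum`: `max(|s|)`
#'   \item `bandpower`: mean periodogram power of the mean-removed signal
#'     over (0, Nyquist], computed with an FFT; by Parseval this equals the
#'     average AC power of the signal.
#'   \item `geometric_mean`: `exp(mean(log(pmax(|s|, eps))))`
#'   \item `maximum` / `median` / `minimum`: order statistics.
#'   \item `rms`: `sqrt(mean(s^2))`; `rss`: `sqrt(sum(s^2))`
#'   \item `shannon_entropy`: signal-energy entropy `-sum(s^2 * log(s^2))`
#'     with `0 * log(0) = 0`.
#' }
#'
#' @param class Feature-class name (a `name` from [feature_classes()]).
#' @param signal Numeric window signal, finite, length >= 2.
#' @param sample_rate Sampling rate, Hz (used by frequency-domain classes).
#' @return A single numeric value.
#' @export
extract_feature <- function(class, signal, sample_rate = 60) {
  if (length(signal) < 2L || any(!is.finite(signal))) {
    stop("signal must be finite with length >= 2", call. = FALSE)
  }
  switch(class,
    abs_harmonic_mean = length(signal) /
      sum(1 / pmax(abs(signal), .feature_eps)),
    abs_maximum = max(abs(signal)),
    bandpower = bandpower_fft(signal),
    geometric_mean = exp(mean(log(pmax(abs(signal), .feature_eps)))),
    maximum = max(signal),
    median = stats::median(signal),
    minimum = min(signal),
    rms = sqrt(mean(signal^2)),
    rss = sqrt(sum(signal^2)),
    shannon_entropy = {
      e <- signal^2
      -sum(ifelse(e > 0, e * log(e), 0))
    },
    stop("unknown feature class: ", class, call. = FALSE)
  )
}

# FFT-periodogram bandpower of the mean-removed signal over (0, Nyquist].
bandpower_fft <- function(signal) {
  n <- length(signal)
  x <- signal - mean(signal)
  p <- Mod(stats::fft(x))^2 / n^2
  sum(p[-1L])
}

#' Extract the full feature matrix of an extremity table
#'
#' For every sample (window x limb) extracts every requested feature class
#' from each of the 11 signals, giving `|classes| * 11` named columns
#' (`"{class}__{signal}"`); 110 for the default catalogue.  Deterministic;
#' row order is preserved.
#'
#' @param table An `extremity_table`.
#' @param classes Feature-class names (default: the full catalogue).
#' @param sample_rate Sampling rate, Hz.
#' @return A `feature_table`: list with `meta` (the table's metadata),
#'   feature matrix `x` and integer `label` vector (median scores).
#' @export
extract_feature_matrix <- function(table, classes = feature_classes()$name,
                                   sample_rate = 60) {
  if (n_samples(table) == 0L) stop("empty extremity table", call. = FALSE)
  sigs <- signal_names()
  cols <- as.vector(outer(classes, sigs,
                          function(cl, sg) paste0(cl, "__", sg)))
  x <- matrix(NA_real_, n_samples(table), length(cols),
              dimnames = list(NULL, cols))
  for (j in seq_along(sigs)) {
    sig_mat <- table$signals[, , j, drop = TRUE]
    if (is.null(dim(sig_mat))) sig_mat <- matrix(sig_mat, nrow = 1L)
    for (cl in classes) {
      col <- paste0(cl, "__", sigs[j])
      x[, col] <- apply(sig_mat, 1L, function(s)
        extract_feature(cl, s, sample_rate))
    }
  }
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature at row %d, column %s",
                 bad[1], cols[bad[2]]), call. = FALSE)
  }
  structure(list(meta = table$meta, x = x,
                 label = as.integer(table$meta$median_score)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

# Row subset of a feature table.
subset_features <- function(ft, idx) {
  structure(list(meta = ft$meta[idx, , drop = FALSE],
                 x = ft$x[idx, , drop = FALSE],
                 label = ft$label[idx]),
            class = "feature_table")
}

#' Fit min-max normalization parameters
#'
#' Records the observed minimum and maximum of every feature column on the
#' fitting partition (training data only, to keep the transform
#' leakage-free).
#'
#' @param features A `feature_table` (training partition).
#' @return A `normalization_params` object (per-column min and max).
#' @export
fit_normalization <- function(features) {
  structure(list(
    min = apply(features$x, 2L, min),
    max = apply(features$x, 2L, max)
  ), class = "normalization_params")
}

#' Apply min-max normalization
#'
#' Maps each column to `(x - min) / (max - min)`; constant training columns
#' (max == min) map to 0; out-of-partition values are clipped to [0, 1].
#'
#' @param features A `feature_table`.
#' @param params A `normalization_params` fitted with [fit_normalization()].
#' @return The normalized `feature_table`.
#' @export
apply_normalization <- function(features, params) {
  if (!identical(colnames(features$x), names(params$min))) {
    stop("feature columns do not match normalization parameters",
         call. = FALSE)
  }
  rng <- params$max - params$min
  x <- sweep(features$x, 2L, params$min, `-`)
  x <- sweep(x, 2L, ifelse(rng > 0, rng, 1), `/`)
  x[, rng == 0] <- 0
  x[x < 0] <- 0
  x[x > 1] <- 1
  out <- features
  out$x <- x
  out
}
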