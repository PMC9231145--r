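# Shared fixtures, built in code at test time.

# A small cohort with strong score/amplitude coupling, suitable for fast
# end-to-end runs.
small_cohort_config <- function(n_subjects = 3L, recordings = 2L,
                                seconds = 30, het = 0, rater_sd = 0,
                                missing = 0, failure = 0, unscorable = 0,
                                seed = 42L) {
  cohort_config(
    n_subjects = n_subjects, recordings_per_subject = recordings,
    recording_seconds = seconds, subject_heterogeneity_sd = het,
    rater_noise_sd = rater_sd, missing_rate = missing,
    sensor_failure_prob = failure, unscorable_rate = unscorable,
    seed = seed)
}

# Cohort -> pooled labelled extremity tables.
cohort_tables <- function(config) {
  co <- generate_cohort(config)
  sync <- synchronize_cohort(co, nominal_rate = config$sample_rate)
  windows <- list()
  for (rec in sync$recordings) {
    windows <- c(windows, suppressWarnings(segment_windows(rec)))
  }
  aligned <- align_labels(windows, co$annotations, strict = FALSE)
  list(cohort = co, tables = build_extremity_tables(aligned$samples),
       aligned = aligned)
}

# Construct a feature_table directly (bypassing signal extraction) for
# selection / training unit tests.
toy_feature_table <- function(x, label, subject_id = NULL) {
  n <- nrow(x)
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  }
  meta <- data.frame(
    subject_id = subject_id %||% rep("S01", n),
    recording_id = rep("R01", n),
    window_index = seq_len(n) - 1L,
    limb = rep("arm_left", n),
    median_score = as.integer(label),
    stringsAsFactors = FALSE)
  structure(list(meta = meta, x = x, label = as.integer(label)),
            class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A feature table where one planted column determines the label and the
# rest are noise.
planted_feature_table <- function(n = 50L, p_noise = 10L, classes = 0:2,
                                  informative_at = 1L, seed = 7L) {
  set.seed(seed)
  label <- rep(classes, length.out = n)
  x <- matrix(runif(n * (p_noise + 1L)), n)
  x[, informative_at] <- label / max(classes) + rnorm(n, sd = 0.01)
  colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  toy_feature_table(x, label)
}

# Build a well-formed uniform sensor stream at `rate` Hz.
uniform_stream <- function(location, n = 600L, rate = 60,
                           values = NULL, seed = 1L) {
  set.seed(seed)
  t_ms <- (seq_len(n) - 1L) * 1000 / rate
  dat <- if (is.null(values)) {
    matrix(rnorm(n * 9L), n, 9L)
  } else {
    matrix(values, n, 9L)
  }
  colnames(dat) <- sensor_channels()
  sensor_stream(location, t_ms, dat)
}

four_uniform_streams <- function(n = 600L, rate = 60, seed = 1L) {
  sts <- lapply(seq_along(limb_locations()), function(i)
    uniform_stream(limb_locations()[i], n = n, rate = rate, seed = seed + i))
  names(sts) <- limb_locations()
  sts
}

# Independent brute-force feature definitions (loops / direct formulas)
# used as oracles against the package's vectorized implementations.
oracle_feature <- function(class, s) {
  n <- length(s)
  eps <- 1e-12
  switch(class,
    abs_harmonic_mean = {
      acc <- 0
      for (v in s) acc <- acc + 1 / max(abs(v), eps)
      n / acc
    },
    abs_maximum = max(abs(s)),
    bandpower = {
      m <- sum(s) / n
      acc <- 0
      for (v in s) acc <- acc + (v - m)^2
      acc / n            # Parseval: mean AC power
    },
    geometric_mean = {
      acc <- 0
      for (v in s) acc <- acc + log(max(abs(v), eps))
      exp(acc / n)
    },
    maximum = max(s),
    median = stats::median(s),
    minimum = min(s),
    rms = sqrt(sum(s^2) / n),
    rss = sqrt(sum(s^2)),
    shannon_entropy = {
      acc <- 0
      for (v in s) if (v != 0) acc <- acc - v^2 * log(v^2)
      acc
    })
}

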