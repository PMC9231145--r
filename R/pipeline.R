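#' Full-run configuration
#'
#' Bundles every effective parameter of an end-to-end run: the synthetic
#' cohort (or an existing cohort directory), windowing, feature catalogue,
#' selection and tuning budgets, CV schemes and the experiment grid.  The
#' defaults reproduce the study protocol settings (60 Hz, 5-s windows,
#' 0.7 screening threshold, SFS budget 20, tuning budget 15, 5-fold /
#' leave-two-subjects-out CV).
#'
#' @param cohort A [cohort_config()] for the simulate stage, or `NULL`
#'   when `input_dir` points at an existing cohort.
#' @param input_dir Existing cohort directory (used when `cohort` is NULL).
#' @param window_seconds Window length, s.
#' @param sample_rate Nominal rate, Hz.
#' @param screening_threshold F1 threshold for feature-class screening.
#' @param run_screening Run the screening stage (off by default: the
#'   default catalogue is the post-screening set).
#' @param extremity `"upper"`, `"lower"` or `"both"`.
#' @param experiment An [experiment_config()].
#' @param run_individual,run_generalized Which experiments to run.
#' @param seed Master seed (overrides the seeds inside `cohort` /
#'   `experiment` so one integer pins the whole run).
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       input_dir = NULL,
                       window_seconds = 5,
                       sample_rate = 60,
                       screening_threshold = 0.7,
                       run_screening = FALSE,
                       extremity = c("upper", "lower", "both"),
                       experiment = experiment_config(),
                       run_individual = TRUE,
                       run_generalized = TRUE,
                       seed = 1L) {
  extremity <- match.arg(extremity)
  if (!is.null(cohort)) cohort$seed <- as.integer(seed)
  experiment$seed <- as.integer(seed)
  experiment$sample_rate <- sample_rate
  list(cohort = cohort, input_dir = input_dir,
       window_seconds = window_seconds, sample_rate = sample_rate,
       screening_threshold = screening_threshold,
       run_screening = run_screening,
       extremity = extremity, experiment = experiment,
       run_individual = run_individual, run_generalized = run_generalized,
       seed = as.integer(seed))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order — simulate (or load), ingest,
#' synchronize, window + label, build extremity tables, featurize,
#' (optionally) screen, train individual and generalized model grids,
#' evaluate — and, when `out` is given, writes the leaderboards, summary
#' and a manifest (config echo plus MD5 hashes of every artifact) so that
#' a rerun with an identical config is bit-identical.
#'
#' @param config A [run_config()].
#' @param out Optional output directory for artifacts.
#' @return A `dys_run`: per-extremity lists of individual experiments and
#'   the generalized experiment, the leaderboards, exclusion counts and
#'   the manifest.
#' @export
run_experiment <- function(config = run_config(), out = NULL) {
  # --- simulate / ingest ---------------------------------------------------
  if (!is.null(config$cohort)) {
    cohort <- generate_cohort(config$cohort)
  } else if (!is.null(config$input_dir)) {
    cohort <- read_cohort(config$input_dir)
  } else {
    stop("either a cohort config or an input directory is required",
         call. = FALSE)
  }
  sync <- synchronize_cohort(cohort, nominal_rate = config$sample_rate)
  # --- preprocess ----------------------------------------------------------
  windows <- list()
  for (rec in sync$recordings) {
    windows <- c(windows, segment_windows(rec, config$window_seconds))
  }
  aligned <- align_labels(windows, cohort$annotations, strict = FALSE)
  tables <- build_extremity_tables(aligned$samples)
  extremities <- if (config$extremity == "both") c("upper", "lower") else
    config$extremity
  results <- list()
  for (ext in extremities) {
    table <- tables[[ext]]
    screening <- NULL
    if (isTRUE(config$run_screening)) {
      screening <- screen_feature_classes(
        table, threshold = config$screening_threshold,
        seed = substream_seed(config$seed, "screen", ext),
        sample_rate = config$sample_rate)
    }
    individual <- NULL
    if (isTRUE(config$run_individual)) {
      individual <- lapply(
        split(seq_len(n_samples(table)), table$meta$subject_id),
        function(idx) run_individual_experiment(subset_table(table, idx),
                                                config$experiment))
    }
    generalized <- NULL
    if (isTRUE(config$run_generalized)) {
      generalized <- run_generalized_experiment(table, config$experiment)
    }
    results[[ext]] <- list(table = table, screening = screening,
                           individual = individual,
                           generalized = generalized)
  }
  run <- structure(list(
    results = results,
    exclusions = list(recordings = sync$excluded,
                      windows = aligned$exclusions),
    leaderboard = build_leaderboards(results),
    config = config
  ), class = "dys_run")
  if (!is.null(out)) run$manifest <- write_run_artifacts(run, out)
  run
}

# Flat Table-4-style leaderboards (subject, dataset, algorithm, model,
# validation F1, test F1/precision/recall).
build_leaderboards <- function(results) {
  ind_rows <- list()
  gen_rows <- list()
  for (ext in names(results)) {
    res <- results[[ext]]
    for (sid in names(res$individual %||% list())) {
      exp <- res$individual[[sid]]
      if (isTRUE(exp$skipped)) {
        ind_rows[[length(ind_rows) + 1L]] <- data.frame(
          subject = sid, dataset = ext, algorithm = "n/a", model = "n/a",
          f1_validation = NA_real_, f1_test = NA_real_,
          precision_test = NA_real_, recall_test = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        b <- exp$best
        ind_rows[[length(ind_rows) + 1L]] <- data.frame(
          subject = sid, dataset = ext, algorithm = b$algorithm,
          model = b$setting, f1_validation = b$validation_f1,
          f1_test = b$test_f1, precision_test = b$test_precision,
          recall_test = b$test_recall, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(res$generalized)) {
      b <- res$generalized$best
      gen_rows[[length(gen_rows) + 1L]] <- data.frame(
        dataset = ext, algorithm = b$algorithm, model = b$setting,
        f1_validation = b$validation_f1, f1_test = b$test_f1,
        precision_test = b$test_precision, recall_test = b$test_recall,
        rmse_test = res$generalized$best$variant$test$rmse,
        stringsAsFactors = FALSE)
    }
  }
  list(individual = if (length(ind_rows)) do.call(rbind, ind_rows),
       generalized = if (length(gen_rows)) do.call(rbind, gen_rows))
}

# Write leaderboards + summary + manifest; returns the manifest.
write_run_artifacts <- function(run, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  fmt_num <- function(df) {
    for (nm in names(df)) if (is.numeric(df[[nm]])) {
      df[[nm]] <- sprintf("%.6f", df[[nm]])
    }
    df
  }
  if (!is.null(run$leaderboard$individual)) {
    p <- file.path(out, "leaderboard_individual.csv")
    utils::write.csv(fmt_num(run$leaderboard$individual), p,
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(run$leaderboard$generalized)) {
    p <- file.path(out, "leaderboard_generalized.csv")
    utils::write.csv(fmt_num(run$leaderboard$generalized), p,
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out, "exclusions.csv")
  utils::write.csv(run$exclusions$windows, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  cfg <- run$config
  cfg$cohort <- if (!is.null(cfg$cohort)) {
    c(unclass(cfg$cohort),
      list(score_transition = NULL,
           score_transition_flat = as.vector(cfg$cohort$score_transition)))
  }
  manifest <- list(
    config = cfg,
    seed = run$config$seed,
    artifacts = stats::setNames(
      as.list(unname(tools::md5sum(paths))), basename(paths)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.dys_run <- function(x, ...) {
  cat("<dys_run>\n")
  for (ext in names(x$results)) {
    res <- x$results[[ext]]
    cat(sprintf("  %s: %d samples", ext, n_samples(res$table)))
    if (!is.null(res$generalized)) {
      cat(sprintf("; generalized best %s/%s test F1=%.3f",
                  res$generalized$best$algorithm,
                  res$generalized$best$setting,
                  res$generalized$best$test_f1))
    }
    cat("\n")
  }
  invisible(x)
}
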