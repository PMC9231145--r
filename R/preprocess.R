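#' Resultant (Euclidean norm) of a 3-axis signal
#'
#' `sqrt(x^2 + y^2 + z^2)` per timestamp, applied identically to free
#' acceleration and angular velocity.
#'
#' @param x,y,z Axis signals (equal length, finite).
#' @return Non-negative resultant signal.
#' @export
compute_resultant <- function(x, y, z) {
  if (any(!is.finite(c(x, y, z)))) stop("non-finite input", call. = FALSE)
  sqrt(x^2 + y^2 + z^2)
}

# 9 raw channels -> the 11 per-sensor signals (with resultants inserted).
derive_signals <- function(mat9) {
  out <- cbind(
    mat9[, c("acc_x", "acc_y", "acc_z"), drop = FALSE],
    acc_resultant = compute_resultant(mat9[, "acc_x"], mat9[, "acc_y"],
                                      mat9[, "acc_z"]),
    mat9[, c("gyro_x", "gyro_y", "gyro_z"), drop = FALSE],
    gyro_resultant = compute_resultant(mat9[, "gyro_x"], mat9[, "gyro_y"],
                                       mat9[, "gyro_z"]),
    mat9[, c("roll", "pitch", "yaw"), drop = FALSE])
  colnames(out) <- signal_names()
  out
}

#' Cut a synchronized recording into consecutive 5-s windows
#'
#' Non-overlapping windows of exactly `window_seconds * nominal_rate`
#' samples (300 at 60 Hz) from the recording start; a trailing remainder
#' shorter than one window is dropped.  Each window carries, per sensor,
#' the 11 derived signals (axes, resultants, Euler angles) and the
#' interpolated fraction of its samples.
#'
#' @param rec A `sync_recording`.
#' @param window_seconds Window length in seconds (default 5, matching the
#'   clinical scoring windows).
#' @return List of windows; each has `window_index` (0-based, matching the
#'   annotation indices), `recording_id`, `subject_id`, `signals` (named
#'   list limb -> samples x 11 matrix) and `interp_fraction` per sensor.
#'   An empty list (with a warning) if the recording is shorter than one
#'   window.
#' @export
segment_windows <- function(rec, window_seconds = 5) {
  n_per <- round(window_seconds * rec$nominal_rate)
  n <- length(rec$common_timestamps)
  n_win <- floor(n / n_per)
  if (n_win < 1L) {
    warning(sprintf("recording %s shorter than one %g-s window; no windows",
                    rec$recording_id, window_seconds))
    return(list())
  }
  derived <- lapply(rec$sensors, derive_signals)
  lapply(seq_len(n_win), function(w) {
    idx <- ((w - 1L) * n_per + 1L):(w * n_per)
    list(
      window_index = w - 1L,
      recording_id = rec$recording_id,
      subject_id = rec$subject_id,
      signals = lapply(derived, function(m) m[idx, , drop = FALSE]),
      interp_fraction = vapply(rec$interpolated,
                               function(f) mean(f[idx]), numeric(1))
    )
  })
}

#' Median of three rater scores
#'
#' The final label of a window is the middle order statistic of the three
#' clinicians' integer scores (always itself an integer).
#'
#' @param scores Exactly three non-missing integer scores in 0--4.
#' @return Integer median score.
#' @export
median_rater_score <- function(scores) {
  if (length(scores) != 3L || anyNA(scores)) {
    stop("exactly three non-missing rater scores required", call. = FALSE)
  }
  if (any(!scores %in% 0:4)) stop("scores must be in 0..4", call. = FALSE)
  as.integer(sort(scores)[2L])
}

#' Link clinical scores to signal windows
#'
#' Produces one labelled sample per (window, limb) that has all three rater
#' scores; (window, limb) pairs lacking any rater's score are dropped and
#' counted.  With `strict = TRUE` an annotation addressing a window index
#' that does not exist in the segmented recording is a data error; with
#' `strict = FALSE` (the pipeline default, where sensor failures truncate
#' recordings after the videos were scored) such annotations are dropped
#' and counted too.
#'
#' @param windows Windows from [segment_windows()] (possibly from several
#'   recordings).
#' @param annotations Annotation data frame from [read_annotation_csv()].
#' @param strict Error on annotations addressing nonexistent windows?
#' @return List with `samples` (labelled windows: limb signals, the three
#'   rater scores, median score) and `exclusions` (data frame of dropped
#'   (window, limb) pairs with reasons).
#' @export
align_labels <- function(windows, annotations, strict = TRUE) {
  win_key <- vapply(windows, function(w)
    paste(w$recording_id, w$window_index), character(1))
  win_by_key <- stats::setNames(seq_along(windows), win_key)
  samples <- list()
  exclusions <- list()
  drop <- function(rid, w, limb, reason) {
    exclusions[[length(exclusions) + 1L]] <<- data.frame(
      recording_id = rid, window_index = w, limb = limb, reason = reason,
      stringsAsFactors = FALSE)
  }
  groups <- split(annotations,
                  list(annotations$recording_id, annotations$window_index,
                       annotations$limb), drop = TRUE)
  # deterministic order: recording, window, limb
  ord <- order(vapply(groups, function(g) g$recording_id[1], character(1)),
               vapply(groups, function(g) g$window_index[1], integer(1)),
               vapply(groups, function(g) g$limb[1], character(1)))
  for (g in groups[ord]) {
    rid <- g$recording_id[1]
    w <- g$window_index[1]
    limb <- g$limb[1]
    key <- paste(rid, w)
    if (!key %in% names(win_by_key)) {
      if (strict) {
        stop(sprintf("annotation references nonexistent window %d of %s",
                     w, rid), call. = FALSE)
      }
      drop(rid, w, limb, "window not present in recording")
      next
    }
    if (nrow(g) < 3L || anyNA(g$score)) {
      drop(rid, w, limb, "missing rater score")
      next
    }
    win <- windows[[win_by_key[[key]]]]
    if (!limb %in% names(win$signals)) {
      drop(rid, w, limb, "sensor missing for limb")
      next
    }
    samples[[length(samples) + 1L]] <- list(
      recording_id = rid,
      subject_id = win$subject_id,
      window_index = w,
      limb = limb,
      signals = win$signals[[limb]],
      rater_scores = as.integer(g$score[1:3]),
      median_score = median_rater_score(as.integer(g$score[1:3])),
      interp_fraction = win$interp_fraction[[limb]]
    )
  }
  list(samples = samples,
       exclusions = if (length(exclusions)) do.call(rbind, exclusions) else
         data.frame(recording_id = character(), window_index = integer(),
                    limb = character(), reason = character()))
}

#' Assemble upper- and lower-extremity sample tables
#'
#' Pools labelled windows of the left and right limbs of each extremity:
#' the upper table holds arm_left + arm_right samples, the lower table
#' leg_left + leg_right.  Each row keeps only the 11 signals of its own
#' limb's sensor.
#'
#' @param labelled Labelled samples (the `samples` element of
#'   [align_labels()]).
#' @return List with elements `upper` and `lower`, each an
#'   `extremity_table`: `meta` data frame (subject, recording, window,
#'   limb, rater scores, median score, interpolated-fraction flag) plus a
#'   samples x 300 x 11 signal array.
#' @export
build_extremity_tables <- function(labelled) {
  make_table <- function(extremity, limbs) {
    rows <- Filter(function(s) s$limb %in% limbs, labelled)
    if (length(rows) == 0L) {
      return(structure(list(extremity = extremity,
                            meta = data.frame(), signals = NULL),
                       class = "extremity_table"))
    }
    n_samp <- nrow(rows[[1]]$signals)
    sig <- array(NA_real_, c(length(rows), n_samp, 11L),
                 dimnames = list(NULL, NULL, signal_names()))
    for (i in seq_along(rows)) sig[i, , ] <- rows[[i]]$signals
    meta <- data.frame(
      subject_id = vapply(rows, `[[`, character(1), "subject_id"),
      recording_id = vapply(rows, `[[`, character(1), "recording_id"),
      window_index = vapply(rows, `[[`, integer(1), "window_index"),
      limb = vapply(rows, `[[`, character(1), "limb"),
      rater1 = vapply(rows, function(r) r$rater_scores[1], integer(1)),
      rater2 = vapply(rows, function(r) r$rater_scores[2], integer(1)),
      rater3 = vapply(rows, function(r) r$rater_scores[3], integer(1)),
      median_score = vapply(rows, `[[`, integer(1), "median_score"),
      interp_fraction = vapply(rows, `[[`, numeric(1), "interp_fraction"),
      stringsAsFactors = FALSE)
    # heavily interpolated windows are flagged but retained
    meta$high_interp <- meta$interp_fraction > 0.5
    structure(list(extremity = extremity, meta = meta, signals = sig),
              class = "extremity_table")
  }
  list(upper = make_table("upper", c("arm_left", "arm_right")),
       lower = make_table("lower", c("leg_left", "leg_right")))
}

#' @export
print.extremity_table <- function(x, ...) {
  cat(sprintf("<extremity_table> %s: %d samples x %d signals\n",
              x$extremity, nrow(x$meta),
              if (is.null(x$signals)) 0L else dim(x$signals)[3]))
  if (nrow(x$meta)) {
    tab <- table(factor(x$meta$median_score, levels = 0:4))
    cat("  score counts:", paste(sprintf("%s:%d", names(tab), tab),
                                 collapse = " "), "\n")
  }
  invisible(x)
}

# Number of rows in an extremity table.
n_samples <- function(table) nrow(table$meta)

# Row subset of an extremity table (keeps class and alignment).
subset_table <- function(table, idx) {
  structure(list(extremity = table$extremity,
                 meta = table$meta[idx, , drop = FALSE],
                 signals = table$signals[idx, , , drop = FALSE]),
            class = "extremity_table")
}
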