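#' Construct a sensor stream
#'
#' One body-worn sensor's timestamped 9-channel record: free acceleration
#' (m/s^2, gravity removed by the sensor's fusion algorithm), angular
#' velocity (deg/s) and Euler angles (deg, roll/pitch/yaw, ZYX sequence).
#'
#' @param sensor_location One of [limb_locations()].
#' @param timestamps Strictly increasing timestamps, milliseconds.
#' @param data Numeric matrix, `length(timestamps)` x 9, columns
#'   [sensor_channels()].
#' @return Object of class `sensor_stream`.
#' @export
sensor_stream <- function(sensor_location, timestamps, data) {
  if (!sensor_location %in% limb_locations()) {
    stop("unknown sensor location: ", sensor_location, call. = FALSE)
  }
  data <- as.matrix(data)
  if (nrow(data) != length(timestamps)) {
    stop("channel length must match timestamps", call. = FALSE)
  }
  if (ncol(data) != 9L) stop("sensor data must have 9 channels", call. = FALSE)
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("non-finite sensor values", call. = FALSE)
  colnames(data) <- sensor_channels()
  structure(list(sensor_location = sensor_location,
                 timestamps = as.numeric(timestamps),
                 data = data),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s: %d samples, %.1f s\n", x$sensor_location,
              length(x$timestamps),
              diff(range(x$timestamps)) / 1000))
  invisible(x)
}

#' Write a sensor stream as CSV
#'
#' Dialect: header `timestamp_ms,acc_x,...,yaw`, UTF-8, decimal point,
#' 17 significant digits (lossless double round trip).
#'
#' @param stream A `sensor_stream`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(stream, path) {
  df <- cbind(timestamp_ms = stream$timestamps, stream$data)
  lines <- c(paste(c("timestamp_ms", sensor_channels()), collapse = ","),
             apply(df, 1L, function(row) paste(sprintf("%.17g", row),
                                               collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sensor CSV file
#'
#' Duplicate timestamps are collapsed to the mean of their rows with a
#' warning; a non-monotone timestamp order after deduplication is a data
#' error.
#'
#' @param path Path to a sensor CSV (see [write_sensor_csv()] for the
#'   dialect).
#' @param location Sensor location to attach to the stream.
#' @return A `sensor_stream`.
#' @export
read_sensor_csv <- function(path, location = "arm_left") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("timestamp_ms", sensor_channels())
  if (!identical(names(df), expected)) {
    stop(sprintf("malformed sensor CSV header in %s (expected %s)",
                 path, paste(expected, collapse = ",")), call. = FALSE)
  }
  if (anyDuplicated(df$timestamp_ms)) {
    warning(sprintf("%s: duplicate timestamps collapsed to their mean", path))
    df <- stats::aggregate(df[-1L], by = df["timestamp_ms"], FUN = mean)
  }
  o <- order(df$timestamp_ms)
  df <- df[o, , drop = FALSE]
  if (anyNA(df)) stop("missing values in sensor file ", path, call. = FALSE)
  mat <- as.matrix(df[, -1L])
  rownames(mat) <- NULL
  sensor_stream(location, df$timestamp_ms, mat)
}

#' Read a clinical-score annotation CSV
#'
#' Dialect: `recording_id,window_index,rater_id,limb,score,missing`; `limb`
#' one of [limb_locations()]; `score` an integer 0--4, or blank with
#' `missing=1` for windows the raters could not score (limb not visible).
#' Rows with a score outside 0--4 are rejected with a row-numbered error.
#'
#' @param path Path to the annotation CSV.
#' @return Data frame of annotation records; unscorable rows keep `NA`
#'   scores and `missing == 1`.
#' @export
read_annotation_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(score = "character"))
  required <- c("recording_id", "window_index", "rater_id", "limb", "score")
  if (!all(required %in% names(df))) {
    stop("malformed annotation CSV header in ", path, call. = FALSE)
  }
  if (!"missing" %in% names(df)) df$missing <- 0L
  bad_limb <- !df$limb %in% limb_locations()
  if (any(bad_limb)) {
    stop(sprintf("unknown limb label '%s' at row %d of %s",
                 df$limb[which(bad_limb)[1]], which(bad_limb)[1], path),
         call. = FALSE)
  }
  blank <- df$score == "" | is.na(df$score)
  score <- suppressWarnings(as.integer(df$score))
  bad <- !blank & (is.na(score) | score < 0L | score > 4L)
  if (any(bad)) {
    stop(sprintf("score out of range 0-4 at row %d of %s",
                 which(bad)[1], path), call. = FALSE)
  }
  if (any(blank & !(df$missing %in% 1L))) {
    stop("blank score without missing=1 marker in ", path, call. = FALSE)
  }
  df$score <- ifelse(blank, NA_integer_, score)
  df$window_index <- as.integer(df$window_index)
  df$missing <- as.integer(df$missing)
  df
}

#' Synchronize four sensor streams onto a common uniform grid
#'
#' The common grid runs at `nominal_rate` over the intersection of all
#' sensors' observed time ranges; each channel is linearly interpolated
#' onto it from adjacent observed timestamps, with no extrapolation.
#' Orientation channels are interpolated on the unwrapped angle and then
#' rewrapped to [-180, 180), so interpolation across the +/-180 seam does
#' not pass through 0.  If a sensor fails early the recording is truncated
#' to the common overlap and flagged degraded.
#'
#' @param streams Named list of `sensor_stream`s (names = limb locations).
#' @param nominal_rate Grid rate, Hz.
#' @param recording_id,subject_id Metadata carried through.
#' @return Object of class `sync_recording`: `common_timestamps` (ms),
#'   per-sensor 9-column matrices aligned to the grid, per-sensor logical
#'   `interpolated` flags (grid points more than 1 ms from any raw
#'   timestamp), and `degraded` flags.
#' @export
synchronize_streams <- function(streams, nominal_rate = 60,
                                recording_id = "rec", subject_id = "subj") {
  streams <- Filter(function(s) length(s$timestamps) >= 2L, streams)
  if (length(streams) == 0L) {
    stop("unsynchronizable recording: no usable sensor stream", call. = FALSE)
  }
  starts <- vapply(streams, function(s) s$timestamps[1L], numeric(1))
  ends <- vapply(streams, function(s) s$timestamps[length(s$timestamps)],
                 numeric(1))
  t0 <- max(starts)
  t1 <- min(ends)
  step <- 1000 / nominal_rate
  if (t1 - t0 < step) {
    stop("unsynchronizable recording: empty overlap across sensors",
         call. = FALSE)
  }
  grid <- t0 + step * seq(0L, floor((t1 - t0) / step + 1e-9))
  grid[grid > t1] <- t1  # guard the endpoint against fp overshoot
  # a sensor whose coverage ends well before the global maximum failed early
  degraded <- (ends - t1) > 5 * step | (t0 - starts) > 5 * step
  sensors <- list()
  interp <- list()
  angle_cols <- c("roll", "pitch", "yaw")
  for (nm in names(streams)) {
    s <- streams[[nm]]
    out <- matrix(NA_real_, length(grid), 9L,
                  dimnames = list(NULL, sensor_channels()))
    for (ch in sensor_channels()) {
      y <- s$data[, ch]
      if (ch %in% angle_cols) {
        out[, ch] <- wrap_degrees(
          stats::approx(s$timestamps, unwrap_degrees(y), xout = grid,
                        rule = 1)$y)
      } else {
        out[, ch] <- stats::approx(s$timestamps, y, xout = grid, rule = 1)$y
      }
    }
    nearest <- vapply(grid, function(g) min(abs(s$timestamps - g)), numeric(1))
    sensors[[nm]] <- out
    interp[[nm]] <- nearest > 1.0
  }
  missing_sensors <- setdiff(limb_locations(), names(streams))
  structure(list(
    recording_id = recording_id,
    subject_id = subject_id,
    common_timestamps = grid,
    nominal_rate = nominal_rate,
    sensors = sensors,
    interpolated = interp,
    degraded = stats::setNames(as.logical(degraded), names(streams)),
    missing_sensors = missing_sensors
  ), class = "sync_recording")
}

#' @export
print.sync_recording <- function(x, ...) {
  cat(sprintf("<sync_recording> %s (%s): %d grid points @ %g Hz, %d sensors\n",
              x$recording_id, x$subject_id, length(x$common_timestamps),
              x$nominal_rate, length(x$sensors)))
  if (length(x$missing_sensors)) {
    cat("  missing sensors:", paste(x$missing_sensors, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a synchronized recording
#'
#' Reports duration, per-sensor interpolated fraction and degraded flags;
#' recordings shorter than `min_seconds` are marked unusable.
#'
#' @param rec A `sync_recording`.
#' @param min_seconds Minimum usable duration, seconds.
#' @return List with `duration_s`, `interpolated_fraction` (named),
#'   `degraded`, `missing_sensors` and logical `usable`.
#' @export
validate_recording <- function(rec, min_seconds = 5) {
  duration <- diff(range(rec$common_timestamps)) / 1000
  frac <- vapply(rec$interpolated, mean, numeric(1))
  list(
    recording_id = rec$recording_id,
    duration_s = duration,
    interpolated_fraction = frac,
    degraded = rec$degraded,
    missing_sensors = rec$missing_sensors,
    usable = duration >= min_seconds
  )
}

#' Synchronize every recording of an ingested cohort
#'
#' Convenience wrapper: runs [synchronize_streams()] over a cohort (from
#' [generate_cohort()] or [read_cohort()]), excluding recordings with an
#' empty four-sensor overlap and counting the exclusions, mirroring how
#' unsynchronizable home recordings are lost in practice.
#'
#' @param cohort A cohort list with `recordings`.
#' @param nominal_rate Grid rate, Hz.
#' @return List with `recordings` (sync_recordings) and `excluded` (data
#'   frame of recording_id + reason).
#' @export
synchronize_cohort <- function(cohort, nominal_rate = 60) {
  out <- list()
  excluded <- list()
  for (rec in cohort$recordings) {
    sync <- tryCatch(
      synchronize_streams(rec$streams, nominal_rate = nominal_rate,
                          recording_id = rec$recording_id,
                          subject_id = rec$subject_id),
      error = function(e) e)
    if (inherits(sync, "error")) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        recording_id = rec$recording_id, reason = conditionMessage(sync),
        stringsAsFactors = FALSE)
    } else {
      out[[rec$recording_id]] <- sync
    }
  }
  list(recordings = out,
       excluded = if (length(excluded)) do.call(rbind, excluded) else
         data.frame(recording_id = character(), reason = character()))
}
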