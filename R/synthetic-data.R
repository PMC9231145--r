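#' Configuration for a synthetic dystonia cohort
#'
#' Defines the generative model for a simulated home-measurement cohort:
#' per-limb severity scores evolve as a first-order Markov chain over the
#' 0--4 clinical scale, limb movement is an oscillatory component whose
#' amplitude grows with the true score, subjects differ by a log-normal
#' amplitude factor, three noisy integer raters score every 5-s window, and
#' recordings suffer missing timestamps, whole-sensor failures and
#' unscorable windows.
#'
#' @param n_subjects Number of simulated subjects.
#' @param recordings_per_subject Recordings (one "video" each) per subject.
#' @param recording_seconds Duration of each recording, seconds.
#' @param sample_rate Nominal sampling rate, Hz.
#' @param score_transition 5x5 row-stochastic matrix over scores 0--4.
#' @param amplitude_per_score Movement-amplitude multiplier per true score
#'   (length 5, non-negative). The default `c(0, 0.5, 1, 2, 4)` spaces
#'   adjacent classes geometrically so that they overlap under noise.
#' @param subject_heterogeneity_sd SD of the log-scale subject amplitude
#'   factor (`exp(N(0, sd))`).
#' @param rater_noise_sd SD of each rater's Gaussian error before rounding
#'   and clipping to 0--4.
#' @param noise_sd SD of the baseline Gaussian sensor noise, channel units.
#' @param missing_rate Probability that any timestamp is dropped.
#' @param sensor_failure_prob Probability that a sensor stream is truncated
#'   at a uniformly random point (whole-sensor failure).
#' @param unscorable_rate Probability that a (window, limb) cannot be scored
#'   by the raters (limb not visible on video).
#' @param seed Master seed; all randomness flows from it through named
#'   substreams (per subject / recording / limb).
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 12L,
                          recordings_per_subject = 10L,
                          recording_seconds = 60,
                          sample_rate = 60,
                          score_transition = default_score_transition(),
                          amplitude_per_score = c(0, 0.5, 1, 2, 4),
                          subject_heterogeneity_sd = 0.3,
                          rater_noise_sd = 0.3,
                          noise_sd = 0.05,
                          missing_rate = 0.02,
                          sensor_failure_prob = 0.05,
                          unscorable_rate = 0.02,
                          seed = 1L) {
  stopifnot_scalar_count(n_subjects, "n_subjects")
  stopifnot_scalar_count(recordings_per_subject, "recordings_per_subject")
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` must be > 0", call. = FALSE)
  }
  if (!is.numeric(recording_seconds) || recording_seconds <= 0) {
    stop("`recording_seconds` must be > 0", call. = FALSE)
  }
  check_transition_matrix(score_transition)
  if (length(amplitude_per_score) != 5L || any(amplitude_per_score < 0)) {
    stop("`amplitude_per_score` must be 5 non-negative reals", call. = FALSE)
  }
  for (nm in c("subject_heterogeneity_sd", "rater_noise_sd", "noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      stop(sprintf("`%s` must be a non-negative scalar", nm), call. = FALSE)
    }
  }
  for (nm in c("missing_rate", "sensor_failure_prob", "unscorable_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v >= 1) {
      stop(sprintf("`%s` must be in [0, 1)", nm), call. = FALSE)
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    recordings_per_subject = as.integer(recordings_per_subject),
    recording_seconds = recording_seconds,
    sample_rate = sample_rate,
    score_transition = score_transition,
    amplitude_per_score = amplitude_per_score,
    subject_heterogeneity_sd = subject_heterogeneity_sd,
    rater_noise_sd = rater_noise_sd,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    sensor_failure_prob = sensor_failure_prob,
    unscorable_rate = unscorable_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default severity transition matrix
#'
#' Sticky Markov chain over scores 0--4: probability 0.6 of staying,
#' the remainder split over the adjacent scores, so that severity
#' fluctuates slowly between windows as it does clinically.
#'
#' @return A 5x5 row-stochastic matrix.
#' @export
default_score_transition <- function() {
  P <- matrix(0, 5, 5, dimnames = list(0:4, 0:4))
  for (i in 1:5) {
    P[i, i] <- 0.6
    nb <- intersect(c(i - 1L, i + 1L), 1:5)
    P[i, nb] <- 0.4 / length(nb)
  }
  P
}

check_transition_matrix <- function(P) {
  if (!is.matrix(P) || !all(dim(P) == c(5L, 5L)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("`score_transition` must be a 5x5 row-stochastic matrix", call. = FALSE)
  }
  invisible(P)
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Sample a severity score sequence
#'
#' Realizes a first-order Markov chain over scores 0--4 from
#' `config$score_transition`, starting from the chain's stationary
#' distribution.
#'
#' @param config A [cohort_config()].
#' @param n_windows Number of 5-s windows to score.
#' @param seed Seed for this substream.
#' @param init_state Optional forced initial score 0--4; the default draws
#'   it from the chain's stationary distribution.
#' @return Integer vector of length `n_windows`, values in 0--4.
#' @export
sample_score_sequence <- function(config, n_windows, seed = config$seed,
                                  init_state = NULL) {
  stopifnot_scalar_count(n_windows, "n_windows")
  P <- check_transition_matrix(config$score_transition)
  with_seed(seed, {
    s <- integer(n_windows)
    s[1] <- if (is.null(init_state)) {
      sample(0:4, 1L, prob = stationary_distribution(P))
    } else {
      as.integer(init_state)
    }
    if (n_windows > 1L) {
      for (k in 2:n_windows) {
        s[k] <- sample(0:4, 1L, prob = P[s[k - 1L] + 1L, ])
      }
    }
    s
  })
}

#' Synthesize one limb's sensor stream from a score sequence
#'
#' Per 5-s window the acceleration and angular-velocity channels carry
#' baseline Gaussian noise plus an oscillatory dystonia component: the sum
#' of two sinusoids with frequencies drawn uniformly in 0.5--3 Hz and
#' random phases, with amplitude `amplitude_per_score[score] *
#' subject_factor`.  Orientation channels are the integral of angular
#' velocity (cumulative sum times dt) wrapped to [-180, 180).
#'
#' @param true_scores Integer scores 0--4, one per window.
#' @param config A [cohort_config()].
#' @param subject_factor Positive per-subject amplitude factor.
#' @param location Sensor location (one of [limb_locations()]).
#' @param seed Substream seed.
#' @return A `sensor_stream` (see [sensor_stream()]).
#' @export
synthesize_limb_signal <- function(true_scores, config, subject_factor = 1,
                                   location = "arm_left",
                                   seed = config$seed) {
  if (any(!true_scores %in% 0:4)) stop("scores must be in 0..4", call. = FALSE)
  rate <- config$sample_rate
  n_per <- round(5 * rate)
  n_win <- length(true_scores)
  n <- n_win * n_per
  dt <- 1 / rate
  t_s <- (seq_len(n) - 1L) * dt
  with_seed(seed, {
    motion_cols <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
    dat <- matrix(stats::rnorm(n * 9L, sd = config$noise_sd), n, 9L,
                  dimnames = list(NULL, sensor_channels()))
    for (w in seq_len(n_win)) {
      amp <- config$amplitude_per_score[true_scores[w] + 1L] * subject_factor
      idx <- ((w - 1L) * n_per + 1L):(w * n_per)
      freqs <- stats::runif(2L, 0.5, 3.0)
      for (ch in motion_cols) {
        phases <- stats::runif(2L, 0, 2 * pi)
        osc <- (amp / 2) * (sin(2 * pi * freqs[1] * t_s[idx] + phases[1]) +
                            sin(2 * pi * freqs[2] * t_s[idx] + phases[2]))
        dat[idx, ch] <- dat[idx, ch] + osc
      }
    }
    # orientation follows the gyro: integrated angular velocity, wrapped
    for (k in 1:3) {
      dat[, 6L + k] <- wrap_degrees(cumsum(dat[, 3L + k]) * dt)
    }
    sensor_stream(location, t_s * 1000, dat)
  })
}

#' Simulate three clinician raters for one window
#'
#' Each rater reports `round(true_score + N(0, rater_noise_sd))` clipped to
#' the 0--4 scale.
#'
#' @param true_score Integer 0--4.
#' @param rater_noise_sd Non-negative rater noise SD.
#' @param n_raters Number of raters (default 3).
#' @param seed Optional substream seed; `NULL` uses the current RNG state.
#' @return Integer vector of ratings in 0--4.
#' @export
simulate_raters <- function(true_score, rater_noise_sd, n_raters = 3L,
                            seed = NULL) {
  if (!true_score %in% 0:4) stop("true_score must be in 0..4", call. = FALSE)
  draw <- function() {
    pmin(4L, pmax(0L, as.integer(round(true_score +
      stats::rnorm(n_raters, 0, rater_noise_sd)))))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Inject acquisition artifacts into a sensor stream
#'
#' Drops each timestamp independently with probability `missing_rate` and,
#' with probability `sensor_failure_prob`, truncates the stream at a
#' uniformly random point (whole-sensor failure).  Emitted timestamps stay
#' strictly increasing.
#'
#' @param stream A `sensor_stream`.
#' @param config A [cohort_config()].
#' @param seed Substream seed.
#' @return The degraded `sensor_stream`.
#' @export
inject_artifacts <- function(stream, config, seed = config$seed) {
  with_seed(seed, {
    n <- length(stream$timestamps)
    keep <- stats::runif(n) >= config$missing_rate
    keep[1L] <- TRUE  # anchor the stream start
    if (stats::runif(1) < config$sensor_failure_prob && n > 2L) {
      cut <- sample.int(n - 1L, 1L) + 1L
      keep[cut:n] <- FALSE
    }
    sensor_stream(stream$sensor_location,
                  stream$timestamps[keep],
                  stream$data[keep, , drop = FALSE])
  })
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws per-subject amplitude factors `exp(N(0, subject_heterogeneity_sd))`,
#' simulates per-limb score sequences, synthesizes and degrades the four
#' sensor streams of every recording, and simulates three raters per
#' (window, limb) with occasional unscorable windows.  Deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: list with `recordings` (each holding
#'   four `sensor_stream`s), `annotations` (data frame in the annotation CSV
#'   dialect), `ground_truth` (recording_id, window_index, limb, true_score),
#'   `subjects` (subject_id, amplitude_factor) and the `config` echo.
#' @seealso [write_cohort()], [read_cohort()] for the round-trippable disk
#'   representation.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_win <- floor(config$recording_seconds / 5)
  if (n_win < 1L) stop("recording_seconds must cover at least one 5-s window",
                       call. = FALSE)
  limbs <- limb_locations()
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(config$n_subjects)),
    amplitude_factor = vapply(seq_len(config$n_subjects), function(s) {
      with_seed(substream_seed(config$seed, "subject", s),
                exp(stats::rnorm(1, 0, config$subject_heterogeneity_sd)))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  recordings <- list()
  ann <- list()
  gt <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- subjects$subject_id[s]
    factor_s <- subjects$amplitude_factor[s]
    for (r in seq_len(config$recordings_per_subject)) {
      rid <- sprintf("%s_R%02d", sid, r)
      streams <- list()
      for (limb in limbs) {
        scores <- sample_score_sequence(
          config, n_win, seed = substream_seed(config$seed, "scores", sid, r, limb))
        stream <- synthesize_limb_signal(
          scores, config, subject_factor = factor_s, location = limb,
          seed = substream_seed(config$seed, "signal", sid, r, limb))
        streams[[limb]] <- inject_artifacts(
          stream, config, seed = substream_seed(config$seed, "artifact", sid, r, limb))
        gt[[length(gt) + 1L]] <- data.frame(
          recording_id = rid, window_index = seq_len(n_win) - 1L,
          limb = limb, true_score = scores, stringsAsFactors = FALSE)
        unscorable <- with_seed(
          substream_seed(config$seed, "unscorable", sid, r, limb),
          stats::runif(n_win) < config$unscorable_rate)
        ratings <- with_seed(
          substream_seed(config$seed, "raters", sid, r, limb),
          vapply(scores, simulate_raters, integer(3),
                 rater_noise_sd = config$rater_noise_sd))
        for (w in seq_len(n_win)) {
          sc <- if (unscorable[w]) rep(NA_integer_, 3L) else ratings[, w]
          ann[[length(ann) + 1L]] <- data.frame(
            recording_id = rid, window_index = w - 1L,
            rater_id = sprintf("rater_%d", 1:3), limb = limb,
            score = sc, missing = as.integer(unscorable[w]),
            stringsAsFactors = FALSE)
        }
      }
      recordings[[rid]] <- list(recording_id = rid, subject_id = sid,
                                streams = streams,
                                nominal_rate = config$sample_rate)
    }
  }
  structure(list(
    recordings = recordings,
    annotations = do.call(rbind, ann),
    ground_truth = do.call(rbind, gt),
    subjects = subjects,
    config = config
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d recordings, %d annotation rows\n",
              nrow(x$subjects), length(x$recordings), nrow(x$annotations)))
  invisible(x)
}

#' Write a cohort to disk in the sensor/annotation CSV dialects
#'
#' One directory per subject with one sensor CSV per (recording, limb);
#' cohort-level `annotations.csv`, `ground_truth.csv`, `subjects.csv` and a
#' `manifest.json` (subjects, recordings, file paths keyed by location,
#' config echo).  Numeric values are written with 17 significant digits so
#' the round trip through [read_cohort()] is exact.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest_recs <- list()
  for (rec in cohort$recordings) {
    sdir <- file.path(dir, rec$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    paths <- list()
    for (limb in names(rec$streams)) {
      p <- file.path(sdir, sprintf("%s_%s.csv", rec$recording_id, limb))
      write_sensor_csv(rec$streams[[limb]], p)
      paths[[limb]] <- p
    }
    manifest_recs[[rec$recording_id]] <- list(
      recording_id = rec$recording_id, subject_id = rec$subject_id,
      nominal_rate = rec$nominal_rate,
      sensor_files = lapply(paths, function(p) basename(file.path(
        basename(dirname(p)), basename(p)))),
      sensor_paths = lapply(paths, function(p)
        file.path(basename(dirname(p)), basename(p)))
    )
  }
  ann <- cohort$annotations
  ann$score <- ifelse(is.na(ann$score), "", as.character(ann$score))
  utils::write.csv(ann, file.path(dir, "annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  subj <- cohort$subjects
  subj$amplitude_factor <- sprintf("%.17g", subj$amplitude_factor)
  utils::write.csv(subj, file.path(dir, "subjects.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- unclass(cohort$config)
  cfg$score_transition <- as.vector(cfg$score_transition)
  jsonlite::write_json(
    list(subjects = cohort$subjects$subject_id,
         recordings = unname(manifest_recs),
         config = cfg),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return A list with `recordings` (sensor streams keyed by limb),
#'   `annotations`, `ground_truth` (if present) and the manifest.
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  recordings <- list()
  for (m in man$recordings) {
    streams <- list()
    for (limb in names(m$sensor_paths)) {
      streams[[limb]] <- read_sensor_csv(file.path(dir, m$sensor_paths[[limb]]),
                                         location = limb)
    }
    recordings[[m$recording_id]] <- list(
      recording_id = m$recording_id, subject_id = m$subject_id,
      streams = streams, nominal_rate = m$nominal_rate)
  }
  gt_path <- file.path(dir, "ground_truth.csv")
  list(
    recordings = recordings,
    annotations = read_annotation_csv(file.path(dir, "annotations.csv")),
    ground_truth = if (file.exists(gt_path)) {
      utils::read.csv(gt_path, stringsAsFactors = FALSE)
    },
    manifest = man
  )
}
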