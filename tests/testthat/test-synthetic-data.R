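test_that("score sequences follow the transition matrix", {
  cfg_id <- small_cohort_config()
  cfg_id$score_transition <- diag(5)
  s <- sample_score_sequence(cfg_id, 50L, seed = 1, init_state = 2L)
  expect_identical(unique(s), 2L)

  cfg_u <- small_cohort_config()
  cfg_u$score_transition <- matrix(0.2, 5, 5)
  s <- sample_score_sequence(cfg_u, 1e5L, seed = 3)
  freq <- as.numeric(table(factor(s, levels = 0:4)) / length(s))
  expect_true(all(abs(freq - 0.2) < 0.01))

  s1 <- sample_score_sequence(small_cohort_config(), 1L, seed = 5)
  expect_length(s1, 1L)
  expect_true(s1 %in% 0:4)

  cfg_bad <- small_cohort_config()
  cfg_bad$score_transition <- matrix(1, 5, 5)
  expect_error(sample_score_sequence(cfg_bad, 3L), "stochastic")
})

test_that("synthesized limb signals encode severity in amplitude", {
  cfg <- small_cohort_config()
  cfg$amplitude_per_score <- rep(0, 5)
  cfg$noise_sd <- 0
  st <- synthesize_limb_signal(c(0L, 3L), cfg, seed = 1)
  expect_true(all(st$data[, c("acc_x", "acc_y", "acc_z",
                              "gyro_x", "gyro_y", "gyro_z")] == 0))

  cfg <- small_cohort_config()
  st <- synthesize_limb_signal(c(0L, 4L), cfg, seed = 2)
  expect_identical(nrow(st$data), 600L)   # 300 samples per 5-s window at 60 Hz
  a_r <- compute_resultant(st$data[, "acc_x"], st$data[, "acc_y"],
                           st$data[, "acc_z"])
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(a_r[301:600]), rms(a_r[1:300]))
})

test_that("mean windowed RMS of resultant acceleration increases with score", {
  cfg <- small_cohort_config(seed = 9)
  scores <- rep(0:4, each = 100)
  st <- synthesize_limb_signal(scores, cfg, seed = 11)
  a_r <- compute_resultant(st$data[, "acc_x"], st$data[, "acc_y"],
                           st$data[, "acc_z"])
  win_rms <- vapply(seq_along(scores), function(w)
    sqrt(mean(a_r[((w - 1) * 300 + 1):(w * 300)]^2)), numeric(1))
  means <- tapply(win_rms, scores, mean)
  expect_true(all(diff(means) > 0))
})

test_that("simulated raters are noisy, clipped and median-consistent", {
  expect_identical(simulate_raters(3L, 0, seed = 1), rep(3L, 3L))
  set.seed(2)
  draws <- replicate(500, simulate_raters(0L, 2))
  expect_true(all(draws >= 0L & draws <= 4L))
  set.seed(3)
  med <- replicate(1e4, sort(simulate_raters(2L, 0.5))[2L])
  expect_gte(mean(med == 2L), 0.8)
})

test_that("artifact injection drops and truncates as configured", {
  cfg0 <- small_cohort_config()
  st <- uniform_stream("arm_left", n = 1e4L)
  expect_identical(inject_artifacts(st, cfg0, seed = 1)$timestamps,
                   st$timestamps)

  cfg <- small_cohort_config(missing = 0.1)
  out <- inject_artifacts(st, cfg, seed = 2)
  expect_true(abs(length(out$timestamps) - 9000) <= 150)
  expect_true(all(diff(out$timestamps) > 0))

  cfg$sensor_failure_prob <- 1 - 1e-12
  out <- inject_artifacts(st, cfg, seed = 3)
  expect_lt(length(out$timestamps), length(st$timestamps))
})

test_that("cohort generation is deterministic with per-subject factors", {
  cfg <- small_cohort_config(n_subjects = 12L, recordings = 1L, seconds = 5,
                             het = 0)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
  expect_identical(nrow(co1$subjects), 12L)
  expect_true(all(co1$subjects$amplitude_factor == 1))
  # exactly one true score per (recording, window, limb)
  key <- with(co1$ground_truth, paste(recording_id, window_index, limb))
  expect_identical(anyDuplicated(key), 0L)

  d1 <- file.path(tempdir(), "coh1")
  write_cohort(co1, d1)
  expect_length(list.dirs(d1, recursive = FALSE), 12L)
})

test_that("a written cohort round-trips through the ingest readers", {
  cfg <- small_cohort_config(n_subjects = 2L, recordings = 1L, seconds = 10,
                             het = 0.4, rater_sd = 0.3, missing = 0.05,
                             unscorable = 0.1, seed = 5)
  co <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "cohrt")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  for (rid in names(co$recordings)) {
    for (limb in limb_locations()) {
      orig <- co$recordings[[rid]]$streams[[limb]]
      got <- back$recordings[[rid]]$streams[[limb]]
      expect_identical(got$timestamps, orig$timestamps)
      expect_identical(got$data, orig$data)
    }
  }
  expect_identical(back$annotations$score, co$annotations$score)
  expect_identical(back$ground_truth$true_score, co$ground_truth$true_score)
})
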