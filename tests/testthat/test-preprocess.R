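test_that("resultants are Euclidean norms", {
  expect_identical(compute_resultant(3, 4, 0), 5)
  expect_identical(compute_resultant(0, 0, 0), 0)
  expect_equal(compute_resultant(1, 1, 1), sqrt(3), tolerance = 1e-12)
  expect_error(compute_resultant(1, NA, 2), "finite")
})

test_that("windowing partitions the recording into 300-sample blocks", {
  rec <- synchronize_streams(four_uniform_streams(n = 65 * 60))
  wins <- segment_windows(rec)
  expect_length(wins, 13L)
  for (w in wins) {
    expect_identical(nrow(w$signals$arm_left), 300L)
    expect_identical(ncol(w$signals$arm_left), 11L)
  }
  # contiguous non-overlapping partition of the recording prefix
  recon <- do.call(rbind, lapply(wins, function(w)
    w$signals$arm_left[, c(1:3, 5:7, 9:11)]))
  expect_equal(unname(recon),
               unname(rec$sensors$arm_left[seq_len(13L * 300L), ]),
               tolerance = 1e-12)

  short <- synchronize_streams(four_uniform_streams(n = 290L))
  expect_warning(w0 <- segment_windows(short), "shorter")
  expect_length(w0, 0L)
})

test_that("derived windows expose 44 signals across the four sensors", {
  rec <- synchronize_streams(four_uniform_streams(n = 300L))
  w <- segment_windows(rec)[[1]]
  expect_identical(sum(vapply(w$signals, ncol, integer(1))), 44L)
  # resultant dominance
  for (nm in names(w$signals)) {
    s <- w$signals[[nm]]
    expect_true(all(s[, "acc_resultant"] >=
                      apply(abs(s[, c("acc_x", "acc_y", "acc_z")]), 1, max) -
                      1e-12))
  }
})

test_that("median rater score is the middle order statistic", {
  expect_identical(median_rater_score(c(1L, 2L, 4L)), 2L)
  expect_identical(median_rater_score(c(0L, 0L, 4L)), 0L)
  expect_identical(median_rater_score(c(3L, 3L, 3L)), 3L)
  expect_error(median_rater_score(c(1L, 2L)), "three")
  expect_error(median_rater_score(c(1L, NA, 2L)), "three")
  # permutation invariance
  set.seed(1)
  for (i in 1:20) {
    s <- sample(0:4, 3L, replace = TRUE)
    expect_identical(median_rater_score(s), median_rater_score(sample(s)))
  }
})

test_that("label alignment links scores to windows and counts exclusions", {
  rec <- synchronize_streams(four_uniform_streams(n = 12L * 300L))
  wins <- segment_windows(rec)
  grid <- expand.grid(w = 0:11, limb = limb_locations(), r = 1:3,
                      stringsAsFactors = FALSE)
  ann <- data.frame(recording_id = "rec", window_index = grid$w,
                    rater_id = sprintf("rater_%d", grid$r), limb = grid$limb,
                    score = 2L, missing = 0L, stringsAsFactors = FALSE)
  al <- align_labels(wins, ann)
  expect_length(al$samples, 48L)

  ann2 <- ann
  ann2$score[ann2$window_index == 0 & ann2$limb == "arm_left" &
               ann2$rater_id == "rater_1"] <- NA_integer_
  al2 <- align_labels(wins, ann2)
  expect_length(al2$samples, 47L)
  expect_identical(nrow(al2$exclusions), 1L)

  ann3 <- ann
  ann3$window_index[1] <- 99L
  expect_error(align_labels(wins, ann3), "99")
  al3 <- align_labels(wins, ann3, strict = FALSE)
  expect_true("window not present in recording" %in% al3$exclusions$reason)
})

test_that("noise-free raters reproduce the generator's ground truth", {
  cfg <- small_cohort_config(n_subjects = 2L, recordings = 1L, seconds = 30,
                             rater_sd = 0, seed = 21)
  res <- cohort_tables(cfg)
  gt <- res$cohort$ground_truth
  for (ext in c("upper", "lower")) {
    meta <- res$tables[[ext]]$meta
    key_gt <- with(gt, paste(recording_id, window_index, limb))
    truth <- gt$true_score[match(
      with(meta, paste(recording_id, window_index, limb)), key_gt)]
    expect_identical(meta$median_score, truth)
  }
})

test_that("extremity tables pool left and right limbs per extremity", {
  cfg <- small_cohort_config(n_subjects = 1L, recordings = 1L, seconds = 50,
                             seed = 22)
  res <- cohort_tables(cfg)
  expect_identical(nrow(res$tables$upper$meta), 20L)  # 10 windows x 2 arms
  expect_identical(nrow(res$tables$lower$meta), 20L)
  expect_true(all(res$tables$upper$meta$limb %in% c("arm_left", "arm_right")))
  expect_true(all(res$tables$lower$meta$limb %in% c("leg_left", "leg_right")))
  expect_identical(dim(res$tables$upper$signals)[2:3], c(300L, 11L))

  # a failed left-arm sensor leaves only right-arm rows in the upper table
  co <- res$cohort
  rec <- co$recordings[[1]]
  rec$streams$arm_left <- NULL
  sync <- synchronize_streams(rec$streams, recording_id = rec$recording_id,
                              subject_id = rec$subject_id)
  wins <- segment_windows(sync)
  al <- align_labels(wins, co$annotations, strict = FALSE)
  tabs <- build_extremity_tables(al$samples)
  expect_identical(unique(tabs$upper$meta$limb), "arm_right")
})
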