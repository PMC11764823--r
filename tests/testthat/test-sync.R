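test_that("clap detection finds the global maximum above prominence", {
  pw <- rep(1000, 100)
  pw[37] <- 4000
  expect_equal(detect_clap_peak(pw, 0, 20, sample_rate = 5), 37L)

  expect_error(detect_clap_peak(rep(1000, 100), 0, 20, sample_rate = 5),
               class = "kineat_no_clap")

  two <- rep(1000, 100)
  two[20] <- 3500; two[60] <- 4000
  expect_equal(detect_clap_peak(two, 0, 20, sample_rate = 5), 60L)

  # ties break toward the earliest index
  tie <- rep(1000, 100)
  tie[30] <- 4000; tie[70] <- 4000
  expect_equal(detect_clap_peak(tie, 0, 20, sample_rate = 5), 30L)
})

test_that("clock offsets follow the clap-time arithmetic", {
  expect_equal(align_streams(50, 5, 275, 25, index_origin = 0), 1.0)
  expect_equal(align_streams(51, 5, 276, 25, index_origin = 1), 1.0)
  expect_equal(align_streams(25, 5, 125, 25, index_origin = 0), 0)
  expect_error(align_streams(-1, 5, 10, 25), "origin")
})

test_that("shifting the audio envelope shifts the offset by exactly k frames", {
  meal <- simulate_subject_meal(default_profiles("04", 1),
                                duration_per_item_s = 20, seed = 2)
  base <- segment_offsets(meal$streams$dominant, meal$audio_envelope)
  for (k in c(5L, 25L, 50L)) {
    shifted <- c(rep(0, k),
                 meal$audio_envelope[seq_len(length(meal$audio_envelope) - k)])
    attributes(shifted) <- attributes(meal$audio_envelope)
    got <- segment_offsets(meal$streams$dominant, shifted)
    expect_equal(got$offset_s, base$offset_s + k / 25, tolerance = 1e-9)
  }
})

test_that("injected clock offsets are recovered within one accelerometer sample", {
  # moderately noisy meals, offsets across [-5, 5] s
  set.seed(99)
  offsets <- runif(20, -5, 5)
  for (i in seq_along(offsets)) {
    prof <- profile_with("06", effect_size = 1, noise_sd_mG = 200)
    meal <- simulate_subject_meal(list(prof), duration_per_item_s = 20,
                                  seed = 100 + i,
                                  audio_offset_s = offsets[i])
    got <- segment_offsets(meal$streams$dominant, meal$audio_envelope)
    expect_lt(abs(got$offset_s - offsets[i]), 0.2 + 1e-9)
  }
})

test_that("annotation times round-trip through the recovered offset", {
  off <- 2.3
  meal <- simulate_subject_meal(default_profiles("08", 1),
                                duration_per_item_s = 30, seed = 4,
                                audio_offset_s = off)
  ann <- simulate_annotators(meal$truth, jitter_sd_s = 0, seed = 1,
                             clock_offset_s = off)
  rec <- segment_offsets(meal$streams$dominant, meal$audio_envelope)
  labels <- rasterize_intervals(ann$a$intervals, meal$streams$dominant$t_s,
                                offset_s = rec)
  truth_labels <- rasterize_intervals(meal$truth, meal$streams$dominant$t_s)
  # the recovered offset is exact up to audio frame rounding (0.04 s), so
  # at most a boundary sample per interval may flip
  expect_gt(mean(labels == truth_labels), 0.99)
})
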