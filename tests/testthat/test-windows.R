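test_that("window specs map widths to sample counts at 5 Hz", {
  expect_equal(vapply(1:5, function(w) window_spec(w)$samples_per_window,
                      0L),
               c(5L, 10L, 15L, 20L, 25L))
  expect_error(window_spec(6), "1..5")
  expect_error(window_spec(2, step_s = 0.5), "integer")
})

test_that("window enumeration matches the closed-form count and brute force", {
  expect_length(enumerate_windows(10, window_spec(1)), 10)
  expect_length(enumerate_windows(10, window_spec(5)), 6)
  expect_length(enumerate_windows(3, window_spec(5)), 0)

  brute <- function(L, w, s) {
    starts <- c()
    t <- 0
    while (t + w <= L) {
      starts <- c(starts, t)
      t <- t + s
    }
    starts
  }
  set.seed(13)
  for (i in 1:100) {
    L <- sample(0:40, 1)
    w <- sample(1:5, 1)
    s <- sample(1:3, 1)
    got <- enumerate_windows(L, window_spec(w, step_s = s))
    expect_equal(got, as.numeric(brute(L, w, s)),
                 label = sprintf("L=%d w=%d s=%d", L, w, s))
  }
})

test_that("window slopes equal closed-form OLS and behave linearly", {
  expect_equal(window_slope(rep(7, 5), 5), 0)
  expect_equal(window_slope(c(0, 0.2, 0.4, 0.6, 0.8), 5), 1.0)
  expect_equal(window_slope(c(0, 1, 2, 3, 4), 5), 5.0)

  # against lm() as the independent oracle
  set.seed(17)
  for (i in 1:50) {
    n <- sample(c(5, 10, 15, 20, 25), 1)
    v <- rnorm(n, sd = 100)
    t <- (seq_len(n) - 1) / 5
    expect_equal(window_slope(v, 5),
                 unname(coef(lm(v ~ t))[2]), tolerance = 1e-10)
  }

  # linearity and shift invariance
  v <- rnorm(15)
  expect_equal(window_slope(3 * v + 11, 5), 3 * window_slope(v, 5),
               tolerance = 1e-12)
  expect_error(window_slope(c(1), 5), "at least 2")
  expect_error(window_slope(c(1, NA), 5), "non-finite")
})

test_that("IU construction obeys the strict majority rule and feature layouts", {
  # one 4 s segment at 5 Hz with hand-built labels
  n <- 20
  frame <- data.frame(subject_id = "S01", wrist = "dominant",
                      segment_id = "S01-01", food_id = "01",
                      t_s = (0:(n - 1)) / 5,
                      x_mG = rnorm(n), y_mG = rnorm(n),
                      z_mG = 1000 + rnorm(n))
  frame <- derive_kinetics(frame)
  nd <- frame
  nd$wrist <- "nondominant"

  # 3 of 5 samples eating -> eating; exactly half -> not eating
  lab_a <- rep(FALSE, n); lab_a[3:5] <- TRUE     # window 1 has 3/5
  lab_b <- rep(FALSE, n); lab_b[c(3:5, 9:10)] <- TRUE
  fused <- combine_labels(lab_a, lab_b)
  ius1 <- build_ius(list(dominant = frame), fused, window_spec(1),
                    "dominant")
  expect_true(ius1$eating_united[1])          # 3/5 united
  expect_true(ius1$eating_intersected[1])     # 3/5 intersected
  ius2 <- build_ius(list(dominant = frame), fused, window_spec(2),
                    "dominant")
  # window [1,3) holds samples 6..10: united eating at 9,10 plus 0 -> 2/10
  expect_false(ius2$eating_united[2])
  # window [0,2): united samples 3,4,5 = 3/10; exactly 5/10 would not count
  lab_half <- rep(FALSE, n); lab_half[1:5] <- TRUE
  half <- combine_labels(lab_half, lab_half)
  ius_half <- build_ius(list(dominant = frame), half, window_spec(2),
                        "dominant")
  expect_false(ius_half$eating_united[1])     # exactly 50% is not a majority

  dom <- build_ius(list(dominant = frame), fused, window_spec(1),
                   "dominant")
  expect_length(iu_features(dom), 7)
  full <- build_ius(list(dominant = frame, nondominant = nd), fused,
                    window_spec(1), "full")
  expect_length(iu_features(full), 14)
  expect_identical(iu_features(full)[1:7],
                   paste0("dominant_",
                          c("x", "y", "z", "pitch", "roll", "power",
                            "total_energy"), "_slope"))
  expect_equal(nrow(full), nrow(dom))

  bad <- nd[-1, ]
  expect_error(build_ius(list(dominant = frame, nondominant = bad), fused,
                         window_spec(1), "full"), "misaligned")
})

test_that("IU totals follow the per-segment window formula on a study", {
  ius <- small_ius(3)
  study <- small_study()
  seg_len <- study$duration_per_item_s
  n_segments <- sum(vapply(study$subjects, function(s)
    nrow(s$meal$segments), 0L))
  expect_equal(nrow(ius), n_segments * (seg_len - 3 + 1))
})

test_that("intersected-eating IUs are a subset of united-eating IUs across widths and seeds", {
  for (seed in 1:6) {
    study <- simulate_study(n_subjects = 1, duration_per_item_s = 20,
                            jitter_sd_s = 0.5, seed = seed)
    prep <- kineat:::.prepare_study(study)
    for (w in c(1, 3, 5)) {
      ius <- kineat:::.study_ius(prep, window_spec(w))
      expect_true(all(ius$eating_intersected <= ius$eating_united),
                  label = sprintf("seed %d width %d", seed, w))
    }
  }
})
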