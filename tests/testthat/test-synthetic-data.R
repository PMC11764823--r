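test_that("gesture profiles follow the registry and the effect-size dial", {
  # two-handed set: taglierini, mozzarella, meatballs, sandwich, stracchino
  two_handed <- c("05", "06", "07", "09", "13")
  for (id in food_registry()$food_id) {
    p <- make_gesture_profile(id, effect_size = 1)
    expect_identical(p$two_handed, id %in% two_handed, label = id)
    expect_lt(p$bite_duration_s, p$bite_period_s)
  }

  # effect 0: all foods share identical kinetic parameters
  kin_fields <- c("bite_period_s", "bite_duration_s", "pitch_amplitude_rad",
                  "roll_amplitude_rad", "linear_accel_burst_mG",
                  "noise_sd_mG", "posture_pitch_rad", "posture_roll_rad")
  null_profiles <- default_profiles(effect_size = 0)
  for (f in kin_fields) {
    vals <- vapply(null_profiles, `[[`, 0, f)
    expect_equal(unname(diff(range(vals))), 0, label = f)
  }

  # effect > 0: parameter vectors pairwise distinct, margins grow with effect
  vecs <- function(e) t(vapply(default_profiles(effect_size = e),
                               function(p) unlist(p[kin_fields]),
                               numeric(length(kin_fields))))
  d1 <- as.matrix(dist(vecs(1)))
  d2 <- as.matrix(dist(vecs(2)))
  off_diag <- upper.tri(d1)
  expect_true(all(d1[off_diag] > 0))
  expect_true(all(d2[off_diag] >= d1[off_diag] - 1e-9))

  expect_error(make_gesture_profile("99"), "01.*13")
  expect_error(make_gesture_profile("07", effect_size = -1))
})

test_that("simulated meals have the expected shape and are seed-deterministic", {
  profs <- default_profiles(c("01", "07"), effect_size = 1)
  meal <- simulate_subject_meal(profs, duration_per_item_s = 60, seed = 3)
  # 5 Hz x 60 s x 2 segments per wrist
  expect_equal(nrow(meal$streams$dominant), 600)
  expect_equal(nrow(meal$streams$nondominant), 600)
  expect_equal(as.vector(table(meal$streams$dominant$segment_id)),
               c(300, 300))
  expect_identical(meal$streams$dominant$segment_id,
                   meal$streams$nondominant$segment_id)

  again <- simulate_subject_meal(profs, duration_per_item_s = 60, seed = 3)
  expect_identical(meal, again)
  other <- simulate_subject_meal(profs, duration_per_item_s = 60, seed = 4)
  expect_false(identical(meal$streams$dominant$x_mG,
                         other$streams$dominant$x_mG))

  expect_error(simulate_subject_meal(list()), "at least one")
  expect_error(simulate_subject_meal(profs, duration_per_item_s = 5),
               ">= 10")
})

test_that("a stationary noise-free baseline reads pure gravity", {
  still <- profile_with("01", pitch_amplitude_rad = 0,
                        roll_amplitude_rad = 0, linear_accel_burst_mG = 0,
                        noise_sd_mG = 0)
  meal <- simulate_subject_meal(list(still), duration_per_item_s = 20,
                                seed = 1)
  for (wrist in c("dominant", "nondominant")) {
    k <- derive_kinetics(meal$streams[[wrist]])
    no_clap <- -(1:2)  # the clap spike occupies the first two samples
    expect_equal(k$power_mG[no_clap], rep(1000, 98), tolerance = 1e-9)
    expect_equal(k$total_energy_mG[no_clap], rep(0, 98), tolerance = 1e-6)
  }
})

test_that("claps mark every segment start in both streams and the audio", {
  meal <- simulate_subject_meal(default_profiles(c("02", "04", "08"), 2),
                                duration_per_item_s = 30, seed = 5)
  expect_equal(meal$clap_times_s, c(0, 30, 60))
  rate <- attr(meal$audio_envelope, "rate_fps")
  t0 <- attr(meal$audio_envelope, "t0_s")
  peaks <- which(meal$audio_envelope == 1)
  expect_equal(t0 + (peaks - 1) / rate, meal$clap_times_s, tolerance = 0.04)
  for (wrist in c("dominant", "nondominant")) {
    s <- meal$streams[[wrist]]
    at_clap <- s$t_s %in% meal$clap_times_s
    expect_true(all(s$x_mG[at_clap] > 2000))
  }
})

test_that("the non-dominant wrist is quiet except for two-handed foods", {
  # food 01 is one-handed, food 07 (meatballs) two-handed
  meal <- simulate_subject_meal(default_profiles(c("01", "07"), 2),
                                duration_per_item_s = 60, seed = 9)
  nd <- derive_kinetics(meal$streams$nondominant)
  sd_by_seg <- tapply(nd$pitch_rad, nd$segment_id, sd)
  one_handed <- grepl("-01$", names(sd_by_seg))
  expect_gt(sd_by_seg[!one_handed], 3 * sd_by_seg[one_handed])
})

test_that("annotator jitter preserves truth structure", {
  meal <- simulate_subject_meal(default_profiles(c("03", "10"), 1),
                                duration_per_item_s = 30, seed = 6)
  t_s <- meal$streams$dominant$t_s

  exact <- simulate_annotators(meal$truth, jitter_sd_s = 0, seed = 1,
                               t_s = t_s)
  truth_labels <- rasterize_intervals(meal$truth, t_s)
  expect_identical(exact$a$labels, truth_labels)
  expect_identical(exact$b$labels, truth_labels)

  for (seed in 1:5) {
    jit <- simulate_annotators(meal$truth, jitter_sd_s = 0.4, seed = seed,
                               t_s = t_s)
    fused <- combine_labels(jit$a, jit$b)
    expect_true(all(fused$intersected <= fused$united))
    expect_true(all(jit$a$intervals$stop_s > jit$a$intervals$start_s))
  }

  none <- simulate_annotators(meal$truth[0, ], jitter_sd_s = 0.3, seed = 2,
                              t_s = t_s)
  expect_false(any(none$a$labels))
  expect_error(simulate_annotators(meal$truth, jitter_sd_s = -1), ">= 0")
})

test_that("food separability increases with the effect-size dial", {
  centroid_spread <- function(e) {
    study <- simulate_study(n_subjects = 4, duration_per_item_s = 30,
                            effect_size = e, seed = 21)
    prep <- kineat:::.prepare_study(study)
    ius <- kineat:::.study_ius(prep, window_spec(5))
    eat <- ius[ius$eating_united, ]
    feats <- iu_features(eat)
    cents <- aggregate(eat[feats], list(food = eat$food_id), mean)
    mean(dist(scale(cents[-1], center = FALSE)))
  }
  spread <- vapply(c(0, 0.5, 1, 2), centroid_spread, 0)
  expect_true(all(diff(spread) >= 0))
})
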