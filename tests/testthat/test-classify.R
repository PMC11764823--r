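test_that("the mtry search covers 1..p and degenerates sensibly", {
  ius <- two_food_ius(n_per_class = 40, p = 4)
  sel <- select_mtry_cv(ius, forest_settings(n_trees = 50, seed = 2))
  expect_equal(sel$accuracy$mtry, 1:4)
  expect_true(sel$mtry %in% 1:4)

  one_feat <- ius[, c("food_id", "dominant_f1_slope")]
  sel1 <- select_mtry_cv(one_feat, forest_settings(n_trees = 50, seed = 2))
  expect_equal(sel1$mtry, 1L)

  single <- ius[ius$food_id == "01", ]
  expect_error(select_mtry_cv(single, forest_settings(n_trees = 50)),
               "2 food classes")
})

test_that("well-separated classes are fit perfectly, matching a centroid oracle", {
  ius <- two_food_ius(n_per_class = 100, gap = 6, seed = 3)
  feats <- iu_features(ius)
  sel <- select_mtry_cv(ius, forest_settings(n_trees = 100, seed = 4))
  expect_equal(max(sel$accuracy$accuracy), 1.0)

  model <- food_forest(ius, forest_settings(n_trees = 100, mtry = sel$mtry,
                                            seed = 4))
  m <- oob_metrics(model)
  expect_equal(m$sensitivity, c(1, 1))
  expect_equal(m$specificity, c(1, 1))

  oracle <- nearest_centroid(ius[feats], ius$food_id, ius[feats])
  expect_equal(mean(oracle == ius$food_id), 1.0)
})

test_that("forests are deterministic in the seed and validate mtry", {
  ius <- two_food_ius(n_per_class = 50, gap = 2, seed = 5)
  s <- forest_settings(n_trees = 60, mtry = 2, seed = 7)
  m1 <- food_forest(ius, s)
  m2 <- food_forest(ius, s)
  expect_identical(oob_predictions(m1), oob_predictions(m2))
  expect_identical(scaled_importance(m1), scaled_importance(m2))

  expect_error(food_forest(ius, forest_settings(n_trees = 60, mtry = 15)),
               "exceeds")
  expect_error(food_forest(ius[0, ], s), "empty")
})

test_that("bootstrap out-of-bag fractions match the 1/e expectation", {
  ius <- two_food_ius(n_per_class = 500, gap = 1, seed = 6)
  model <- food_forest(ius, forest_settings(n_trees = 80, mtry = 2,
                                            seed = 8))
  inbag <- model$forest$inbag
  oob_frac <- colMeans(inbag == 0)
  # P(excluded) = (1 - 1/n)^n -> 1/e ~ 0.368
  expect_gt(mean(oob_frac), 0.33)
  expect_lt(mean(oob_frac), 0.41)
})

test_that("OOB votes are conserved and confusion tallies close", {
  ius <- two_food_ius(n_per_class = 60, gap = 1.5, seed = 9)
  model <- food_forest(ius, forest_settings(n_trees = 50, mtry = 2,
                                            seed = 10))
  rf <- model$forest
  counts <- rf$votes * rf$oob.times
  expect_equal(unname(rowSums(counts)), unname(rf$oob.times),
               tolerance = 1e-9)

  m <- oob_metrics(model)
  pred <- oob_predictions(model)
  for (i in seq_len(nrow(m))) {
    f <- m$food_id[i]
    keep <- !is.na(pred)
    expect_equal(m$support[i], sum(model$y[keep] == f))
  }
})

test_that("importance is min-max scaled and ranks signal above noise", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 150
    ius <- data.frame(
      food_id = rep(c("01", "02"), each = n / 2),
      dominant_signal_slope = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
      dominant_noise_slope = rnorm(n),
      stringsAsFactors = FALSE
    )
    model <- food_forest(ius, forest_settings(n_trees = 60, mtry = 1,
                                              seed = seed))
    imp <- scaled_importance(model)
    expect_equal(sort(imp$scaled_0_100), c(0, 100))
    expect_gt(imp$scaled_0_100[imp$variable == "dominant_signal_slope"],
              imp$scaled_0_100[imp$variable == "dominant_noise_slope"])
  }
})

test_that("prediction methods agree with the underlying forest", {
  ius <- two_food_ius(n_per_class = 60, gap = 5, seed = 11)
  model <- food_forest(ius, forest_settings(n_trees = 60, mtry = 2,
                                            seed = 12))
  pred <- predict(model, ius)
  expect_equal(mean(pred == ius$food_id), 1.0)
  votes <- predict(model, ius, type = "vote")
  expect_equal(colnames(votes), c("01", "02"))
  expect_error(predict(model, ius[, 1:2]), "lacks feature")
})
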