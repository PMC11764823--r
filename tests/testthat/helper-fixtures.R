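# Shared small fixtures, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

# A small but complete study: 4 subjects (two per menu), 30 s per food item.
small_study <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_study(n_subjects = 4,
                                         duration_per_item_s = 30,
                                         effect_size = 2, seed = 42)
  }
  .fixture_env$small
}

# IU table of the small study at a given width, full-source features.
small_ius <- function(width_s = 5) {
  key <- paste0("ius", width_s)
  if (is.null(.fixture_env[[key]])) {
    prep <- kineat:::.prepare_study(small_study())
    .fixture_env[[key]] <- kineat:::.study_ius(prep, window_spec(width_s))
  }
  .fixture_env[[key]]
}

# A gesture profile with chosen fields overridden (for degenerate cases the
# registry-driven constructor cannot produce, e.g. a zero-noise stationary
# baseline).
profile_with <- function(food_id = "01", effect_size = 0, ...) {
  p <- make_gesture_profile(food_id, effect_size)
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

# Two cleanly separated synthetic food classes in IU-table form: class means
# differ by `gap` in every feature.
two_food_ius <- function(n_per_class = 100, gap = 6, sd = 1, p = 4,
                         seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, 0, sd), ncol = p),
             matrix(rnorm(n_per_class * p, gap, sd), ncol = p))
  colnames(x) <- paste0("dominant_f", seq_len(p), "_slope")
  cbind(data.frame(food_id = rep(c("01", "02"), each = n_per_class),
                   stringsAsFactors = FALSE),
        as.data.frame(x))
}

# Nearest-centroid classifier: the independent oracle used to cross-check
# forest results on separable data.
nearest_centroid <- function(train_x, train_y, test_x) {
  cents <- aggregate(train_x, list(y = train_y), mean)
  d <- as.matrix(dist(rbind(as.matrix(cents[-1]), as.matrix(test_x))))
  k <- nrow(cents)
  d <- d[-(seq_len(k)), seq_len(k), drop = FALSE]
  cents$y[max.col(-d, ties.method = "first")]
}
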