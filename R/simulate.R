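# Gesture synthesis constants.
.CLAP_MG <- 3000        # clap spike added to all three axes, 2 samples
.CLAP_SAMPLES <- 2L
.RETURN_S <- 0.4        # hand-return time closing each eating movement
.LEAD_IN_S <- 2         # quiet time between the clap and the first bite
.BURST_DIR <- c(0.36, 0.48, 0.80)  # unit vector of the linear-accel burst
.AUDIO_T0_S <- -8       # audio timeline starts before the watches' t = 0

# Scalar time course of one eating movement: linear rise over the bite
# duration, then a fast linear return. Every kinematic channel follows this
# one profile, scaled by its own amplitude.
.gesture_course <- function(t_seg, bite_starts, duration_s) {
  g <- numeric(length(t_seg))
  for (bs in bite_starts) {
    rel <- t_seg - bs
    up <- rel >= 0 & rel < duration_s
    g[up] <- rel[up] / duration_s
    down <- rel >= duration_s & rel < duration_s + .RETURN_S
    g[down] <- 1 - (rel[down] - duration_s) / .RETURN_S
  }
  g
}

# Project gravity (plus a linear-acceleration term along .BURST_DIR) onto
# the watch axes for orientation (pitch, roll). The convention inverts the
# pitch/roll formulas of derive_kinetics(): the rest pose (0, 0, G) reads
# pitch 0, roll 0.
.project_axes <- function(pitch, roll, linear_mG) {
  list(
    x = -.G_MG * cos(pitch) * sin(roll) + linear_mG * .BURST_DIR[1],
    y = .G_MG * sin(pitch) + linear_mG * .BURST_DIR[2],
    z = .G_MG * cos(pitch) * cos(roll) + linear_mG * .BURST_DIR[3]
  )
}

#' Simulate one subject's meal on both wrists
#'
#' Generates the raw 5 Hz triaxial streams of a meal in which the subject
#' eats the supplied foods one after another, one food-item segment each.
#' Each segment starts with a hand clap (a 2-sample +3000 milli-G spike on
#' all axes of both wrists, mirrored as a single-frame peak in the 25 FPS
#' audio envelope), followed by repeated eating movements: the wrist
#' orientation ramps from the food's eating posture up by the food's pitch
#' and roll amplitudes over the bite duration and snaps back, while a
#' linear-acceleration burst follows the same time course. The accelerometer
#' reads the gravity vector rotated by (pitch, roll) plus that linear term
#' plus Gaussian sensor noise. The non-dominant wrist carries the gesture
#' only for two-handed foods (scaled by \code{min(1, effect_size)}), and
#' baseline noise otherwise, so at effect size 0 the flag leaves the signal
#' statistics untouched.
#'
#' @param profiles List of \code{\link{make_gesture_profile}} objects, one
#'   per food segment, in serving order.
#' @param duration_per_item_s Seconds per food segment (>= 10; default 60).
#' @param sample_rate_hz Watch sampling rate (default 5 Hz).
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @param subject_id Subject identifier used in stream metadata and seed
#'   splitting.
#' @param audio_offset_s Clock offset of the camera relative to the watches
#'   (an event at watch time t appears at audio time t + offset). Used to
#'   exercise the clap-synchronisation stage; default 0.
#' @param audio_rate_fps Camera frame rate (default 25 FPS).
#' @return An object of class \code{synthetic_meal}: list with
#'   \code{streams} (named list \code{dominant}/\code{nondominant} of data
#'   frames with columns \code{subject_id}, \code{wrist}, \code{segment_id},
#'   \code{food_id}, \code{t_s}, \code{x_mG}, \code{y_mG}, \code{z_mG}),
#'   \code{truth} (data frame of eating intervals \code{segment_id},
#'   \code{food_id}, \code{start_s}, \code{stop_s} on the watch clock),
#'   \code{audio_envelope} (nonnegative numeric with attributes
#'   \code{t0_s} and \code{rate_fps}), \code{clap_times_s},
#'   \code{segments}, \code{audio_offset_s} and \code{sample_rate_hz}.
#' @export
simulate_subject_meal <- function(profiles, duration_per_item_s = 60,
                                  sample_rate_hz = 5, seed = 1,
                                  subject_id = "S01", audio_offset_s = 0,
                                  audio_rate_fps = 25) {
  if (length(profiles) == 0) stop("profiles must contain at least one food")
  if (inherits(profiles, "gesture_profile")) profiles <- list(profiles)
  if (!all(vapply(profiles, inherits, TRUE, "gesture_profile"))) {
    stop("profiles must be gesture_profile objects")
  }
  if (duration_per_item_s < 10) {
    stop("duration_per_item_s must be >= 10 s (one food segment must hold ",
         "a clap, a lead-in and at least one eating movement)")
  }
  stopifnot(sample_rate_hz > 0, audio_rate_fps > 0)

  n_seg <- round(duration_per_item_s * sample_rate_hz)
  n_foods <- length(profiles)
  n_total <- n_seg * n_foods
  t_all <- (seq_len(n_total) - 1) / sample_rate_hz

  seg_meta <- data.frame(
    segment_id = paste0(subject_id, "-",
                        vapply(profiles, `[[`, "", "food_id")),
    food_id = vapply(profiles, `[[`, "", "food_id"),
    start_s = (seq_len(n_foods) - 1) * duration_per_item_s,
    len_s = duration_per_item_s,
    stringsAsFactors = FALSE
  )
  clap_times <- seg_meta$start_s

  truth <- NULL
  streams <- list()
  for (wrist in c("dominant", "nondominant")) {
    set.seed(split_seed(seed, subject_id, wrist))
    x <- numeric(n_total); y <- numeric(n_total); z <- numeric(n_total)
    for (k in seq_len(n_foods)) {
      p <- profiles[[k]]
      idx <- ((k - 1) * n_seg + 1):(k * n_seg)
      t_seg <- t_all[idx] - seg_meta$start_s[k]
      gain <- if (wrist == "dominant") 1 else {
        if (p$two_handed) min(1, p$effect_size) else 0
      }
      last_start <- duration_per_item_s - p$bite_duration_s - .RETURN_S
      bite_starts <- if (last_start >= .LEAD_IN_S) {
        seq(.LEAD_IN_S, last_start, by = p$bite_period_s)
      } else numeric(0)
      g <- .gesture_course(t_seg, bite_starts, p$bite_duration_s)
      pitch <- gain * (p$posture_pitch_rad + p$pitch_amplitude_rad * g)
      roll <- gain * (p$posture_roll_rad + p$roll_amplitude_rad * g)
      ax <- .project_axes(pitch, roll, gain * p$linear_accel_burst_mG * g)
      noise <- p$noise_sd_mG
      x[idx] <- ax$x + (if (noise > 0) stats::rnorm(n_seg, 0, noise) else 0)
      y[idx] <- ax$y + (if (noise > 0) stats::rnorm(n_seg, 0, noise) else 0)
      z[idx] <- ax$z + (if (noise > 0) stats::rnorm(n_seg, 0, noise) else 0)
      clap_idx <- idx[seq_len(min(.CLAP_SAMPLES, n_seg))]
      x[clap_idx] <- x[clap_idx] + .CLAP_MG
      y[clap_idx] <- y[clap_idx] + .CLAP_MG
      z[clap_idx] <- z[clap_idx] + .CLAP_MG
      if (wrist == "dominant" && length(bite_starts)) {
        truth <- rbind(truth, data.frame(
          segment_id = seg_meta$segment_id[k],
          food_id = p$food_id,
          start_s = seg_meta$start_s[k] + bite_starts,
          stop_s = seg_meta$start_s[k] + bite_starts + p$bite_duration_s +
            .RETURN_S,
          stringsAsFactors = FALSE
        ))
      }
    }
    streams[[wrist]] <- data.frame(
      subject_id = subject_id,
      wrist = wrist,
      segment_id = rep(seg_meta$segment_id, each = n_seg),
      food_id = rep(seg_meta$food_id, each = n_seg),
      t_s = t_all, x_mG = x, y_mG = y, z_mG = z,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(truth)) {
    truth <- data.frame(segment_id = character(), food_id = character(),
                        start_s = numeric(), stop_s = numeric(),
                        stringsAsFactors = FALSE)
  }

  set.seed(split_seed(seed, subject_id, "audio"))
  audio_len <- ceiling((n_foods * duration_per_item_s - .AUDIO_T0_S +
                          abs(audio_offset_s) + 2) * audio_rate_fps)
  env <- stats::runif(audio_len, 0, 0.02)
  peak_frames <- round((clap_times + audio_offset_s - .AUDIO_T0_S) *
                         audio_rate_fps) + 1
  peak_frames <- peak_frames[peak_frames >= 1 & peak_frames <= audio_len]
  env[peak_frames] <- 1
  attr(env, "t0_s") <- .AUDIO_T0_S
  attr(env, "rate_fps") <- audio_rate_fps

  structure(list(
    streams = streams, truth = truth, audio_envelope = env,
    clap_times_s = clap_times, segments = seg_meta,
    audio_offset_s = audio_offset_s, sample_rate_hz = sample_rate_hz,
    subject_id = subject_id, seed = seed
  ), class = "synthetic_meal")
}

#' @export
print.synthetic_meal <- function(x, ...) {
  cat(sprintf("<synthetic_meal> subject %s: %d food segments, %d samples/wrist at %g Hz\n",
              x$subject_id, nrow(x$segments),
              nrow(x$streams$dominant), x$sample_rate_hz))
  cat(sprintf("  %d eating movements; audio offset %+.2f s\n",
              nrow(x$truth), x$audio_offset_s))
  invisible(x)
}

#' Simulate two video annotators from ground-truth eating intervals
#'
#' Each evaluator reproduces the true eating intervals with independent
#' zero-mean Gaussian jitter on every interval endpoint (human reaction
#' variability when scrubbing video frames), clipped so each interval keeps
#' \code{stop > start}. Interval times are reported on the camera clock
#' (truth shifted by \code{clock_offset_s}); when sample timestamps
#' \code{t_s} are supplied the intervals are also rasterised into per-sample
#' eating labels on the watch clock.
#'
#' @param truth Data frame of true intervals (\code{segment_id},
#'   \code{food_id}, \code{start_s}, \code{stop_s}) on the watch clock.
#' @param jitter_sd_s Endpoint jitter standard deviation in seconds (>= 0;
#'   0 reproduces the truth exactly).
#' @param seed Integer seed.
#' @param t_s Optional watch-clock timestamps to rasterise labels on.
#' @param clock_offset_s Camera-minus-watch clock offset applied to the
#'   reported interval times.
#' @return Named list of two \code{annotation_track} objects (\code{a},
#'   \code{b}), each with \code{evaluator_id}, \code{intervals} (camera
#'   clock) and \code{labels} (logical, or NULL when \code{t_s} is absent).
#' @export
simulate_annotators <- function(truth, jitter_sd_s = 0.3, seed = 1,
                                t_s = NULL, clock_offset_s = 0) {
  if (jitter_sd_s < 0) stop("jitter_sd_s must be >= 0")
  make_track <- function(evaluator) {
    set.seed(split_seed(seed, "annotator", evaluator))
    iv <- truth
    if (nrow(iv)) {
      iv$start_s <- iv$start_s + stats::rnorm(nrow(iv), 0, jitter_sd_s) +
        clock_offset_s
      iv$stop_s <- iv$stop_s + stats::rnorm(nrow(iv), 0, jitter_sd_s) +
        clock_offset_s
      iv$stop_s <- pmax(iv$stop_s, iv$start_s + 0.2)
      iv$evaluator <- evaluator
    } else {
      iv <- data.frame(segment_id = character(), food_id = character(),
                       start_s = numeric(), stop_s = numeric(),
                       evaluator = character(), stringsAsFactors = FALSE)
    }
    labels <- if (!is.null(t_s)) {
      rasterize_intervals(iv, t_s, offset_s = clock_offset_s)
    }
    structure(list(evaluator_id = evaluator, intervals = iv,
                   labels = labels),
              class = "annotation_track")
  }
  list(a = make_track("a"), b = make_track("b"))
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> evaluator %s: %d intervals%s\n",
              x$evaluator_id, nrow(x$intervals),
              if (is.null(x$labels)) "" else
                sprintf(", %d/%d samples eating", sum(x$labels),
                        length(x$labels))))
  invisible(x)
}

#' Simulate a complete study
#'
#' Builds the default study shape: \code{n_subjects} subjects randomly
#' assigned (balanced) to menus A and B, each eating their menu's seven food
#' items in meal order in one continuous recording, on two wrists, with two
#' jittered annotators per subject.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param effect_size Food-separability dial (default 2); see
#'   \code{\link{make_gesture_profile}}.
#' @param duration_per_item_s Seconds per food segment (default 60).
#' @param jitter_sd_s Annotator endpoint jitter (default 0.3 s).
#' @param seed Integer master seed.
#' @param sample_rate_hz Watch sampling rate (default 5 Hz).
#' @param audio_offset_s Camera clock offset, recycled across subjects.
#' @return Object of class \code{eating_study}: list with \code{subjects}
#'   (each a list of \code{meal} and \code{annotations}) and the generating
#'   parameters.
#' @examples
#' study <- simulate_study(n_subjects = 2, duration_per_item_s = 20, seed = 7)
#' study
#' @export
simulate_study <- function(n_subjects = 20, effect_size = 2,
                           duration_per_item_s = 60, jitter_sd_s = 0.3,
                           seed = 1, sample_rate_hz = 5,
                           audio_offset_s = 0) {
  stopifnot(n_subjects >= 1)
  set.seed(split_seed(seed, "menus"))
  menus <- sample(rep(c("A", "B"), c(ceiling(n_subjects / 2),
                                     floor(n_subjects / 2))))
  offsets <- rep_len(audio_offset_s, n_subjects)
  subjects <- vector("list", n_subjects)
  ids <- sprintf("S%02d", seq_len(n_subjects))
  for (i in seq_len(n_subjects)) {
    profiles <- default_profiles(menu_foods(menus[i]), effect_size)
    meal <- simulate_subject_meal(
      profiles, duration_per_item_s = duration_per_item_s,
      sample_rate_hz = sample_rate_hz, seed = split_seed(seed, ids[i]),
      subject_id = ids[i], audio_offset_s = offsets[i]
    )
    ann <- simulate_annotators(
      meal$truth, jitter_sd_s = jitter_sd_s,
      seed = split_seed(seed, ids[i], "ann"),
      t_s = meal$streams$dominant$t_s, clock_offset_s = offsets[i]
    )
    subjects[[i]] <- list(meal = meal, annotations = ann, menu = menus[i])
  }
  names(subjects) <- ids
  structure(list(
    subjects = subjects, n_subjects = n_subjects, effect_size = effect_size,
    duration_per_item_s = duration_per_item_s, jitter_sd_s = jitter_sd_s,
    sample_rate_hz = sample_rate_hz, seed = seed
  ), class = "eating_study")
}

#' @export
print.eating_study <- function(x, ...) {
  n_samp <- sum(vapply(x$subjects, function(s)
    nrow(s$meal$streams$dominant) * 2L, 0L))
  cat(sprintf("<eating_study> %d subjects, %d raw samples across both wrists\n",
              x$n_subjects, n_samp))
  cat(sprintf("  effect size %g, %g s per food item, annotator jitter sd %g s, seed %d\n",
              x$effect_size, x$duration_per_item_s, x$jitter_sd_s, x$seed))
  invisible(x)
}
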