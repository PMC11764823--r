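#' Sliding-window specification
#'
#' Windows are consecutive runs of raw samples of a fixed time-width. At the
#' 5 Hz watch rate the admissible widths 1-5 s hold 5, 10, 15, 20 and 25
#' samples. Windows advance by \code{step_s} (default 1 s) and never cross a
#' food-item segment boundary.
#'
#' @param width_s Integer window width in seconds, one of 1:5.
#' @param step_s Integer step between window starts in seconds (default 1).
#' @param sample_rate_hz Sampling rate (default 5 Hz).
#' @return Object of class \code{window_spec} with fields \code{width_s},
#'   \code{step_s}, \code{sample_rate_hz} and \code{samples_per_window}.
#' @export
window_spec <- function(width_s, step_s = 1, sample_rate_hz = 5) {
  if (!width_s %in% 1:5) stop("width_s must be an integer in 1..5")
  if (step_s < 1 || step_s != round(step_s)) {
    stop("step_s must be a positive integer number of seconds")
  }
  structure(list(width_s = as.integer(width_s), step_s = as.integer(step_s),
                 sample_rate_hz = sample_rate_hz,
                 samples_per_window = as.integer(width_s * sample_rate_hz)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> width %d s (%d samples), step %d s at %g Hz\n",
              x$width_s, x$samples_per_window, x$step_s, x$sample_rate_hz))
  invisible(x)
}

#' Enumerate window start times within a segment
#'
#' All windows \code{[start, start + width]} with \code{start} a multiple of
#' the step and the window fully inside the segment:
#' \code{floor((L - w) / step) + 1} windows for a segment of length L, or
#' none when the segment is shorter than the width.
#'
#' @param segment_len_s Segment length in seconds (>= 0).
#' @param spec A \code{\link{window_spec}}.
#' @return Numeric vector of window start times (seconds from segment
#'   start), possibly empty.
#' @examples
#' length(enumerate_windows(10, window_spec(5)))  # 6
#' @export
enumerate_windows <- function(segment_len_s, spec) {
  stopifnot(inherits(spec, "window_spec"), segment_len_s >= 0)
  if (segment_len_s < spec$width_s) return(numeric(0))
  n <- floor((segment_len_s - spec$width_s) / spec$step_s) + 1
  (seq_len(n) - 1) * spec$step_s
}

#' Ordinary least-squares slope of a window
#'
#' The slope of the regression line of the sampled values against time
#' within the window, with time starting at 0 and advancing by
#' \code{1/sample_rate_hz}: the closed form
#' \code{sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)}, in
#' variable-units per second.
#'
#' @param values Numeric window of >= 2 finite samples.
#' @param sample_rate_hz Sampling rate of the window.
#' @return The slope (units of \code{values} per second).
#' @examples
#' window_slope(c(0, 1, 2, 3, 4), 5)  # 5 per second
#' @export
window_slope <- function(values, sample_rate_hz) {
  if (length(values) < 2) stop("a window needs at least 2 samples")
  if (!all(is.finite(values))) stop("non-finite value inside window")
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive and finite (equal timestamps ",
         "leave the slope undefined)")
  }
  t <- (seq_along(values) - 1) / sample_rate_hz
  tc <- t - mean(t)
  sum(tc * (values - mean(values))) / sum(tc^2)
}

# Slopes of every window of a series at once: window starts are sample
# offsets (0-based); returns one slope per window using the same closed form
# as window_slope(), expressed as a linear filter over the window.
.window_slopes <- function(values, starts_samples, w_samples, rate) {
  t <- (seq_len(w_samples) - 1) / rate
  tc <- t - mean(t)
  coefs <- tc / sum(tc^2)
  idx <- outer(starts_samples, seq_len(w_samples) - 1L, `+`) + 1L
  matrix(values[idx], nrow = length(starts_samples)) %*% coefs
}

#' Build Information Units from kinetic frames
#'
#' Summarises every admissible window of each food-item segment into one
#' Information Unit (IU): the OLS slopes of the seven kinetic variables
#' (order \code{x, y, z, pitch, roll, power, total_energy}) for the
#' dominant wrist, or the dominant-then-nondominant concatenation of both
#' wrists' slopes (14 features) in \code{full} mode. An IU is labeled
#' eating under a criterion when strictly more than 50\% of its samples
#' carry that criterion's per-sample eating label.
#'
#' @param frames Named list of kinetic frames (\code{dominant}, and
#'   \code{nondominant} for full mode): data frames from
#'   \code{\link{derive_kinetics}} with \code{segment_id},
#'   \code{subject_id}, \code{food_id}, \code{t_s} and the seven kinetic
#'   columns, row-aligned across wrists.
#' @param fused A \code{\link{combine_labels}} result aligned with the
#'   dominant frame's rows.
#' @param spec A \code{\link{window_spec}}.
#' @param source_mode \code{"dominant"} (7 features) or \code{"full"}
#'   (14 features).
#' @return Data frame of IUs: \code{segment_id}, \code{subject_id},
#'   \code{food_id}, \code{start_s}, \code{width_s}, \code{eating_united},
#'   \code{eating_intersected}, then feature columns named
#'   \code{<wrist>_<variable>_slope}.
#' @export
build_ius <- function(frames, fused, spec,
                      source_mode = c("dominant", "full")) {
  source_mode <- match.arg(source_mode)
  stopifnot(inherits(spec, "window_spec"), inherits(fused, "fused_labels"))
  dom <- frames$dominant
  if (is.null(dom)) stop("frames$dominant is required")
  wrists <- if (source_mode == "full") c("dominant", "nondominant")
            else "dominant"
  if (source_mode == "full") {
    nd <- frames$nondominant
    if (is.null(nd)) stop("full source mode requires frames$nondominant")
    if (nrow(nd) != nrow(dom) || !isTRUE(all.equal(nd$t_s, dom$t_s))) {
      stop("wrist frames are misaligned (sample counts or timestamps differ)")
    }
  }
  if (length(fused$united) != nrow(dom)) {
    stop("fused labels (", length(fused$united),
         ") are not aligned with the dominant frame (", nrow(dom), " rows)")
  }
  vars <- kinetic_variables()
  rate <- spec$sample_rate_hz
  w <- spec$samples_per_window
  step_samples <- spec$step_s * rate

  seg_rows <- split(seq_len(nrow(dom)), dom$segment_id)
  # preserve stream order of segments
  seg_rows <- seg_rows[unique(dom$segment_id)]
  pieces <- vector("list", length(seg_rows))
  for (s in seq_along(seg_rows)) {
    rows <- seg_rows[[s]]
    n <- length(rows)
    if (n < w) next
    starts <- seq(0L, n - w, by = step_samples)
    feats <- lapply(wrists, function(wr) {
      fr <- frames[[wr]]
      m <- vapply(vars, function(v)
        as.numeric(.window_slopes(fr[[v]][rows], starts, w, rate)),
        numeric(length(starts)))
      m <- matrix(m, nrow = length(starts))
      colnames(m) <- paste0(wr, "_", sub("_(mG|rad)$", "", vars), "_slope")
      m
    })
    feats <- do.call(cbind, feats)
    count_eat <- function(lab) {
      cs <- cumsum(c(0, lab[rows]))
      cs[starts + w + 1] - cs[starts + 1]
    }
    iu <- data.frame(
      segment_id = dom$segment_id[rows[1]],
      subject_id = dom$subject_id[rows[1]],
      food_id = dom$food_id[rows[1]],
      start_s = dom$t_s[rows[1]] + starts / rate,
      width_s = spec$width_s,
      eating_united = count_eat(fused$united) > w / 2,
      eating_intersected = count_eat(fused$intersected) > w / 2,
      stringsAsFactors = FALSE
    )
    pieces[[s]] <- cbind(iu, as.data.frame(feats))
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) {
    stop("no segment is long enough to hold a single ", spec$width_s,
         " s window")
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Names of the feature columns in an IU table
#'
#' @param iu_table A data frame from \code{\link{build_ius}}.
#' @return Character vector of slope feature column names.
#' @export
iu_features <- function(iu_table) {
  grep("_slope$", names(iu_table), value = TRUE)
}
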