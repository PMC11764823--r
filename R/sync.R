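#' Detect a hand-clap peak in a sample series
#'
#' Returns the index of the global maximum of the series inside a search
#' window, provided it rises above the window's median by at least
#' \code{min_prominence} (ties broken toward the earliest index). Clap
#' detection in watch streams operates on the power channel (acceleration
#' magnitude), which is orientation-invariant; for the audio envelope the
#' raw level is used with a prominence matched to its scale.
#'
#' @param series Numeric, nonnegative sample series.
#' @param search_start_s Start of the search window, seconds from the first
#'   sample of \code{series}.
#' @param search_len_s Length of the search window in seconds.
#' @param sample_rate Samples per second of \code{series}.
#' @param min_prominence Required height of the peak above the window
#'   median (default 1000, suited to milli-G power streams).
#' @return Integer index into \code{series} (1-based).
#' @details When no sample exceeds the prominence threshold a condition of
#'   class \code{kineat_no_clap} is signalled, carrying the window bounds.
#' @examples
#' pw <- rep(1000, 100); pw[37] <- 4000
#' detect_clap_peak(pw, 0, 20, sample_rate = 5)
#' @export
detect_clap_peak <- function(series, search_start_s, search_len_s,
                             sample_rate, min_prominence = 1000) {
  stopifnot(sample_rate > 0, min_prominence > 0, search_len_s > 0)
  i0 <- max(1L, floor(search_start_s * sample_rate) + 1L)
  i1 <- min(length(series),
            ceiling((search_start_s + search_len_s) * sample_rate))
  if (i0 > i1) stop("search window [", search_start_s, ", ",
                    search_start_s + search_len_s, "] s lies outside the series")
  window <- series[i0:i1]
  peak <- which.max(window)
  if (window[peak] <= stats::median(window) + min_prominence) {
    stop(structure(class = c("kineat_no_clap", "error", "condition"),
                   list(message = sprintf(
                     "no clap peak above prominence %g in window [%g, %g] s",
                     min_prominence, search_start_s,
                     search_start_s + search_len_s),
                     call = sys.call(-1))))
  }
  i0 + peak - 1L
}

#' Align the watch and camera clocks from clap indices
#'
#' Converts the clap's sample index in the accelerometer stream and its
#' frame index in the audio envelope into one clock offset:
#' \code{offset_s = audio_time - accel_time}. Downstream, annotation times
#' (on the camera clock) minus \code{offset_s} map onto the watch clock.
#'
#' @param accel_clap_idx Clap sample index in the watch stream.
#' @param accel_rate_hz Watch sampling rate (default 5 Hz).
#' @param audio_clap_idx Clap frame index in the audio envelope.
#' @param audio_rate_fps Camera frame rate (default 25 FPS).
#' @param index_origin Index of the sample at time 0 (1 for R-style indices
#'   as returned by \code{\link{detect_clap_peak}}; 0 for zero-based
#'   offsets).
#' @return The clock offset in seconds (camera minus watch).
#' @examples
#' align_streams(50, 5, 275, 25, index_origin = 0)  # 1 s
#' @export
align_streams <- function(accel_clap_idx, accel_rate_hz = 5,
                          audio_clap_idx, audio_rate_fps = 25,
                          index_origin = 1) {
  stopifnot(accel_rate_hz > 0, audio_rate_fps > 0)
  if (accel_clap_idx < index_origin || audio_clap_idx < index_origin) {
    stop("clap indices must not precede the series origin")
  }
  (audio_clap_idx - index_origin) / audio_rate_fps -
    (accel_clap_idx - index_origin) / accel_rate_hz
}

#' Per-segment clock offsets for one subject's meal
#'
#' For every food-item segment, finds the clap spike in the watch power
#' stream (searched in the first seconds of the segment) and the matching
#' peak in the audio envelope (searched around the segment's nominal start,
#' wide enough to absorb offsets up to \code{search_margin_s}), and reports
#' the camera-minus-watch offset.
#'
#' @param stream Data frame of one wrist's raw stream (columns
#'   \code{segment_id}, \code{t_s}, \code{x_mG}, \code{y_mG}, \code{z_mG}).
#' @param audio_envelope Nonnegative numeric with attributes \code{t0_s}
#'   and \code{rate_fps} (as produced by
#'   \code{\link{simulate_subject_meal}}).
#' @param sample_rate_hz Watch sampling rate.
#' @param search_margin_s Half-width of the audio search window around each
#'   segment's nominal start (default 6 s).
#' @param audio_prominence Peak prominence for the audio envelope (default
#'   0.5 on a 0-1 level scale).
#' @return Data frame with columns \code{segment_id}, \code{offset_s}.
#' @export
segment_offsets <- function(stream, audio_envelope, sample_rate_hz = 5,
                            search_margin_s = 6, audio_prominence = 0.5) {
  power <- sqrt(stream$x_mG^2 + stream$y_mG^2 + stream$z_mG^2)
  rate_fps <- attr(audio_envelope, "rate_fps") %||% 25
  t0 <- attr(audio_envelope, "t0_s") %||% 0
  seg_ids <- unique(stream$segment_id)
  out <- data.frame(segment_id = seg_ids, offset_s = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(seg_ids)) {
    rows <- which(stream$segment_id == seg_ids[i])
    seg_start <- stream$t_s[rows[1]]
    accel_idx <- detect_clap_peak(power, seg_start,
                                  min(5, length(rows) / sample_rate_hz),
                                  sample_rate_hz)
    # A clap transient can ring across a couple of samples; align on its
    # onset (the first suprathreshold sample of the burst), which is the
    # instant both devices witnessed, not on whichever sample noise made
    # the tallest.
    thresh <- stats::median(power[rows]) + 1000
    while (accel_idx > rows[1] && power[accel_idx - 1] > thresh) {
      accel_idx <- accel_idx - 1L
    }
    accel_time <- stream$t_s[accel_idx]
    audio_start <- seg_start - search_margin_s - t0
    audio_idx <- detect_clap_peak(audio_envelope, audio_start,
                                  2 * search_margin_s + 2, rate_fps,
                                  min_prominence = audio_prominence)
    audio_time <- t0 + (audio_idx - 1) / rate_fps
    out$offset_s[i] <- audio_time - accel_time
  }
  out
}
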