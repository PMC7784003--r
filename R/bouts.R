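# Walking-bout detection from the lumbar sensor.
#
# The FoG detector only operates inside walking bouts of at least 10 s. The
# bout detector here is a transparent stand-in for the (unpublished) detector
# of the original pipeline: moving RMS of the band-passed (0.5-3 Hz) lumbar
# gyroscope magnitude, thresholded with hysteresis, with brief dropouts
# bridged. All parameters are exposed and the defaults are calibrated against
# the synthetic-signal generator's amplitude scale.

#' Walking-bout detector parameters
#'
#' @param low_hz,high_hz Locomotor band edges (Hz) for the band-pass filter
#'   applied to the lumbar gyroscope magnitude.
#' @param rms_window_s Length (s) of the centered moving-RMS window.
#' @param on_threshold RMS level (deg/s) that must be reached for a candidate
#'   bout to be accepted (hysteresis upper threshold).
#' @param off_threshold RMS level (deg/s) below which a bout ends (hysteresis
#'   lower threshold; must not exceed `on_threshold`).
#' @param bridge_s Rest gaps strictly shorter than this (s) between active
#'   runs are bridged into one bout.
#' @param min_bout_s Minimum bout duration (s) retained for FoG analysis;
#'   the boundary is inclusive (10 s bouts are kept).
#' @return A list of class `bout_params`.
#' @export
bout_params <- function(low_hz = 0.5, high_hz = 3, rms_window_s = 2,
                        on_threshold = 5, off_threshold = 2.5,
                        bridge_s = 2, min_bout_s = 10) {
  if (low_hz <= 0 || high_hz <= low_hz) stop("need 0 < low_hz < high_hz", call. = FALSE)
  if (off_threshold > on_threshold) stop("off_threshold must be <= on_threshold", call. = FALSE)
  if (min_bout_s < 0 || bridge_s < 0) stop("durations must be non-negative", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz, rms_window_s = rms_window_s,
                 on_threshold = on_threshold, off_threshold = off_threshold,
                 bridge_s = bridge_s, min_bout_s = min_bout_s),
            class = "bout_params")
}

# centered moving mean with shrinking windows at the edges
moving_mean <- function(x, w) {
  n <- length(x)
  half <- floor(w / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(i - half, 1L)
  b <- pmin(i + half, n)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

# activity envelope: band-passed lumbar gyro magnitude -> moving RMS
activity_envelope <- function(recording, params) {
  require_sensors(recording, "lumbar")
  fs <- recording$sampling_rate
  g <- recording$sensors$lumbar$gyro
  mag <- sqrt(rowSums(g^2))
  mag <- mag - mean(mag)
  bf <- signal::butter(2, c(params$low_hz, params$high_hz) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, mag)
  sqrt(moving_mean(bp^2, round(params$rms_window_s * fs)))
}

#' Detect walking bouts from the lumbar sensor
#'
#' Computes the band-passed lumbar gyroscope activity envelope, applies
#' hysteresis thresholding (a run must exceed `on_threshold` somewhere and
#' extends while the envelope stays above `off_threshold`), bridges rest gaps
#' shorter than `bridge_s`, and splits the resulting walking mask at analysis
#' window boundaries. The returned bouts are candidate bouts: apply
#' [filter_bouts()] to impose the minimum-duration criterion.
#'
#' @param recording An `imu_recording` with a lumbar sensor.
#' @param params A [bout_params()] object.
#' @param windows Analysis windows from [segment_windows()]; defaults to
#'   30-min windows over the whole recording.
#' @return data.frame of disjoint ordered bouts with columns `bout_id`,
#'   `window_id`, `start_index`, `end_index` (samples, half-open), `start_s`,
#'   `end_s`, `duration_s`.
#' @export
detect_walking <- function(recording, params = bout_params(), windows = NULL) {
  stopifnot(inherits(recording, "imu_recording"))
  fs <- recording$sampling_rate
  if (is.null(windows)) windows <- segment_windows(recording)
  env <- activity_envelope(recording, params)

  active <- env >= params$off_threshold
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  walking <- logical(length(env))
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && any(env[starts[k]:ends[k]] >= params$on_threshold)) {
      walking[starts[k]:ends[k]] <- TRUE
    }
  }
  # bridge rest gaps strictly shorter than bridge_s between walking runs
  gap_max <- round(params$bridge_s * fs)
  r <- rle(walking)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] && k > 1L && k < length(r$lengths) && r$lengths[k] < gap_max) {
      walking[starts[k]:ends[k]] <- TRUE
    }
  }

  out <- list()
  r <- rle(walking)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    b0 <- starts[k] - 1L  # 0-based half-open
    b1 <- ends[k]
    for (wi in seq_len(nrow(windows))) {
      s <- max(b0, windows$start_index[wi])
      e <- min(b1, windows$end_index[wi])
      if (e > s) {
        out[[length(out) + 1L]] <- data.frame(window_id = windows$window_id[wi],
                                              start_index = s, end_index = e)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(bout_id = integer(0), window_id = integer(0),
                      start_index = integer(0), end_index = integer(0),
                      start_s = numeric(0), end_s = numeric(0), duration_s = numeric(0)))
  }
  bouts <- do.call(rbind, out)
  bouts <- bouts[order(bouts$start_index), , drop = FALSE]
  bouts$start_s <- bouts$start_index / fs
  bouts$end_s <- bouts$end_index / fs
  bouts$duration_s <- bouts$end_s - bouts$start_s
  bouts <- cbind(bout_id = seq_len(nrow(bouts)), bouts)
  rownames(bouts) <- NULL
  bouts
}

#' Keep only bouts of at least a minimum duration
#'
#' The detector analyzes walking bouts of 10 s and longer; the boundary is
#' inclusive. Idempotent; never alters bout boundaries.
#'
#' @param bouts data.frame from [detect_walking()].
#' @param min_bout_s Minimum duration (s), default 10.
#' @return The filtered data.frame, order preserved.
#' @export
filter_bouts <- function(bouts, min_bout_s = 10) {
  bouts[bouts$duration_s >= min_bout_s, , drop = FALSE]
}
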