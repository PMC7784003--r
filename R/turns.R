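# Turn detection from the lumbar yaw (vertical-axis) angular velocity, and
# per-window turning summaries.

#' Turn detector parameters
#'
#' @param velocity_threshold Minimum trunk rotation rate (deg/s) that a turn
#'   core must reach (default 15 deg/s).
#' @param min_turn_angle Minimum unsigned turn angle (deg) for a candidate to
#'   be emitted (default 45 deg; a bare rate criterion would admit sway).
#' @param lowpass_hz Cutoff (Hz) of the low-pass filter applied to the yaw
#'   trace before detection (default 1.5 Hz). Set to `NA` to skip filtering
#'   (e.g. for pre-smoothed or analytically constructed traces).
#' @param merge_gap_s Consecutive same-direction turns separated by less than
#'   this (s) are merged (zero-crossing chatter guard, default 0.1 s).
#' @return A list of class `turn_params`.
#' @export
turn_params <- function(velocity_threshold = 15, min_turn_angle = 45,
                        lowpass_hz = 1.5, merge_gap_s = 0.1) {
  if (velocity_threshold <= 0) stop("velocity_threshold must be positive", call. = FALSE)
  if (min_turn_angle < 0) stop("min_turn_angle must be non-negative", call. = FALSE)
  structure(list(velocity_threshold = velocity_threshold, min_turn_angle = min_turn_angle,
                 lowpass_hz = lowpass_hz, merge_gap_s = merge_gap_s),
            class = "turn_params")
}

#' Detect turns from lumbar yaw angular velocity
#'
#' A turn is a trunk rotation about the vertical axis whose rate reaches the
#' velocity threshold. Candidate cores (contiguous same-sign samples with
#' |yaw| at or above the threshold) are extended outwards to the surrounding
#' zero crossings, nearby same-direction candidates are merged, the turn
#' angle is obtained by trapezoidal integration of the angular rate over the
#' extended segment, and candidates below the minimum angle are discarded.
#'
#' @param x An `imu_recording` with a lumbar sensor, or a numeric yaw trace
#'   in deg/s (then `sampling_rate` is required).
#' @param params A [turn_params()] object.
#' @param sampling_rate Sampling rate (Hz) when `x` is a plain vector.
#' @return data.frame of turns: `turn_id`, `start_s`, `end_s`, `duration_s`,
#'   `angle_deg` (unsigned), `peak_velocity_dps`, `direction` (`left` for
#'   positive yaw, `right` for negative).
#' @export
detect_turns <- function(x, params = turn_params(), sampling_rate = NULL) {
  if (inherits(x, "imu_recording")) {
    require_sensors(x, "lumbar")
    yaw <- x$sensors$lumbar$gyro[, "v"]
    fs <- x$sampling_rate
  } else {
    yaw <- as.numeric(x)
    fs <- sampling_rate
    if (is.null(fs)) stop("`sampling_rate` must be given with a plain yaw trace", call. = FALSE)
  }
  if (is.finite(params$lowpass_hz) && params$lowpass_hz < fs / 2) {
    bf <- signal::butter(2, params$lowpass_hz / (fs / 2), type = "low")
    yaw <- signal::filtfilt(bf, yaw)
  }
  n <- length(yaw)
  empty <- data.frame(turn_id = integer(0), start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), angle_deg = numeric(0),
                      peak_velocity_dps = numeric(0), direction = character(0))
  core <- abs(yaw) >= params$velocity_threshold
  if (!any(core)) return(empty)
  # split contiguous core runs at sign changes
  grp <- cumsum(c(TRUE, diff(core) != 0 | (core[-1] & sign(yaw[-1]) != sign(yaw[-n]))))
  cand <- list()
  for (g in split(seq_len(n), grp)) {
    if (!core[g[1L]]) next
    s <- sign(yaw[g[1L]])
    a <- g[1L]; b <- g[length(g)]
    # extend to surrounding zero crossings (include one exact-zero sample)
    while (a > 1L) {
      v <- yaw[a - 1L]
      if (v * s > 0) a <- a - 1L else { if (v == 0) a <- a - 1L; break }
    }
    while (b < n) {
      v <- yaw[b + 1L]
      if (v * s > 0) b <- b + 1L else { if (v == 0) b <- b + 1L; break }
    }
    cand[[length(cand) + 1L]] <- c(a = a, b = b, s = s)
  }
  if (!length(cand)) return(empty)
  cm <- do.call(rbind, cand)
  cm <- cm[order(cm[, "a"]), , drop = FALSE]
  # drop duplicates (two cores extending to the same segment) and merge
  # same-direction candidates separated by less than merge_gap_s
  gap_max <- params$merge_gap_s * fs
  merged <- list()
  cur <- cm[1L, ]
  if (nrow(cm) > 1L) {
    for (j in 2:nrow(cm)) {
      nxt <- cm[j, ]
      if (nxt["s"] == cur["s"] && nxt["a"] - cur["b"] - 1L <= gap_max) {
        cur["b"] <- max(cur["b"], nxt["b"])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- nxt
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur
  rows <- lapply(merged, function(m) {
    seg <- yaw[m["a"]:m["b"]]
    dt <- 1 / fs
    angle <- abs(dt * (sum(seg) - (seg[1L] + seg[length(seg)]) / 2))
    data.frame(start_s = (m["a"] - 1L) / fs, end_s = m["b"] / fs,
               duration_s = (m["b"] - m["a"] + 1L) / fs,
               angle_deg = angle,
               peak_velocity_dps = max(abs(seg)),
               direction = if (m["s"] > 0) "left" else "right")
  })
  out <- do.call(rbind, rows)
  out <- out[out$angle_deg >= params$min_turn_angle, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- cbind(turn_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Summarize turns per analysis window
#'
#' Reports, for every window, the number of turns and the mean turn angle,
#' duration and peak velocity, plus the coefficient of variation (sample SD
#' over mean) of the peak velocity. Turns are assigned to the window
#' containing their start.
#'
#' @param turns data.frame from [detect_turns()].
#' @param windows data.frame from [segment_windows()].
#' @return data.frame with one row per window: `window_id`, `n_turns`,
#'   `mean_angle_deg`, `mean_duration_s`, `mean_peak_velocity_dps`,
#'   `cv_peak_velocity` (means are NA for windows without turns).
#' @export
summarize_turns <- function(turns, windows) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    ws <- windows$start_s[i]; we <- windows$end_s[i]
    sel <- turns$start_s >= ws & turns$start_s < we
    tt <- turns[sel, , drop = FALSE]
    n <- nrow(tt)
    pk <- tt$peak_velocity_dps
    data.frame(window_id = windows$window_id[i], n_turns = n,
               mean_angle_deg = if (n) mean(tt$angle_deg) else NA_real_,
               mean_duration_s = if (n) mean(tt$duration_s) else NA_real_,
               mean_peak_velocity_dps = if (n) mean(pk) else NA_real_,
               cv_peak_velocity = if (n >= 2 && mean(pk) > 0) stats::sd(pk) / mean(pk) else NA_real_)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
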