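# Core FoG detector: per-second dual-criterion flagging inside walking bouts,
# episode assembly with hesitation merging, and duration categorization.
#
# A 1-s window is a potential freeze by the gyroscope criterion when the
# Pearson correlation between the left and right medio-lateral angular
# velocities falls below 0.5, and by the accelerometer criterion when the
# freeze ratio (spectral energy 3-10 Hz over 0-3 Hz of the antero-posterior
# acceleration) exceeds 10. A window is a FoG window only when both fire.

FOG_CATEGORIES <- c("very_short", "short", "long")

#' FoG detector parameters
#'
#' Houses every threshold of the detector. Defaults are the published
#' operating point: correlation threshold 0.5, freeze-ratio threshold 10,
#' low band (0, 3] Hz, high band (3, 10] Hz, 1-s non-overlapping windows,
#' hesitations of up to 2 s merged.
#'
#' @param corr_threshold Bilateral correlation below which a window is a
#'   potential freeze (in \[-1, 1\]).
#' @param ratio_threshold Freeze ratio above which a window is a potential
#'   freeze (> 0).
#' @param low_band,high_band Frequency bands (Hz) as half-open intervals
#'   `(lo, hi]`; the DC bin is always excluded.
#' @param window_s Analysis window length in s (default 1).
#' @param merge_gap_s Maximum hesitation (s) between freezing segments merged
#'   into a single episode (default 2).
#' @param placement Sensor pair used by the detector: `"feet"` or `"shins"`.
#' @param foot_combination How left/right freeze ratios are combined before
#'   thresholding: `"max"` (default, most sensitive), `"mean"`, or `"either"`
#'   (per-foot thresholding, equivalent to `"max"` at the threshold).
#' @return A list of class `fog_params`.
#' @export
fog_params <- function(corr_threshold = 0.5, ratio_threshold = 10,
                       low_band = c(0, 3), high_band = c(3, 10),
                       window_s = 1, merge_gap_s = 2,
                       placement = c("feet", "shins"),
                       foot_combination = c("max", "mean", "either")) {
  placement <- match.arg(placement)
  foot_combination <- match.arg(foot_combination)
  if (abs(corr_threshold) > 1) stop("corr_threshold must lie in [-1, 1]", call. = FALSE)
  if (ratio_threshold <= 0) stop("ratio_threshold must be positive", call. = FALSE)
  if (window_s <= 0) stop("window_s must be positive", call. = FALSE)
  if (merge_gap_s < 0) stop("merge_gap_s must be non-negative", call. = FALSE)
  if (low_band[2] > high_band[1] + 1e-12 && high_band[1] < low_band[2] - 1e-12) {
    stop("low_band and high_band must not overlap", call. = FALSE)
  }
  structure(list(corr_threshold = corr_threshold, ratio_threshold = ratio_threshold,
                 low_band = as.numeric(low_band), high_band = as.numeric(high_band),
                 window_s = window_s, merge_gap_s = merge_gap_s,
                 placement = placement, foot_combination = foot_combination),
            class = "fog_params")
}

#' Bilateral correlation of left and right medio-lateral gyroscopes
#'
#' Pearson product-moment correlation over one analysis window. During
#' regular walking the left and right leg angular velocities are highly
#' correlated; the correlation drops before and during freezing.
#'
#' If either window has zero variance (a motionless foot mid-bout, consistent
#' with an akinetic arrest) the correlation is undefined and `NA` is
#' returned; callers treat `NA` as a potential freeze so that the freeze-ratio
#' criterion still gates the final decision.
#'
#' @param left,right Numeric vectors of equal length (one window each).
#' @return Correlation in \[-1, 1\], or `NA` for zero-variance input.
#' @export
bilateral_correlation <- function(left, right) {
  if (length(left) != length(right)) {
    stop(sprintf("window lengths differ: %d vs %d", length(left), length(right)), call. = FALSE)
  }
  if (stats::sd(left) == 0 || stats::sd(right) == 0) return(NA_real_)
  stats::cor(left, right)
}

#' Freeze ratio of an antero-posterior acceleration window
#'
#' Ratio of the spectral energy in the high ("freeze") band to that in the
#' low ("locomotor") band of one mean-removed window, computed by FFT. Bands
#' are half-open `(lo, hi]` Hz and the DC bin is excluded, so the gravity
#' component of the accelerometer never enters the ratio. A small guard on
#' the low-band energy keeps the ratio finite (and above any threshold) for
#' pure-tremor windows; an all-zero window yields 0.
#'
#' @param x Numeric window (one analysis window of AP acceleration).
#' @param sampling_rate Sampling rate in Hz.
#' @param low_band,high_band Band intervals `(lo, hi]` in Hz.
#' @return Non-negative ratio.
#' @export
freezing_ratio <- function(x, sampling_rate, low_band = c(0, 3), high_band = c(3, 10)) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * sampling_rate / n
  keep <- f > 0 & f <= sampling_rate / 2  # one-sided spectrum, DC excluded
  e_low <- sum(p[keep & f > low_band[1] & f <= low_band[2]])
  e_high <- sum(p[keep & f > high_band[1] & f <= high_band[2]])
  e_tot <- sum(p[keep])
  if (e_tot == 0) return(0)
  e_high / max(e_low, 1e-12 * e_tot + .Machine$double.xmin)
}

#' Flag FoG windows within one walking bout
#'
#' Tiles the bout with non-overlapping windows of `window_s` starting at the
#' bout's first sample (a trailing fraction shorter than one window is
#' dropped) and evaluates both criteria in each window.
#'
#' @param recording An `imu_recording` containing the sensor pair required by
#'   `params$placement`.
#' @param bout A single bout (one row of the [detect_walking()] output, or any
#'   list with `start_index` and `end_index` in samples, half-open).
#' @param params A [fog_params()] object.
#' @return data.frame with one row per full window: `second_index` (0-based
#'   offset within the bout), `start_s`, `end_s` (absolute), `corr_lr`,
#'   `freeze_ratio_left`, `freeze_ratio_right`, `freeze_ratio` (combined),
#'   `potential_by_corr`, `potential_by_ratio`, `is_fog`.
#' @export
flag_fog_windows <- function(recording, bout, params = fog_params()) {
  stopifnot(inherits(recording, "imu_recording"))
  locs <- placement_locations(params$placement)
  require_sensors(recording, locs)
  fs <- recording$sampling_rate
  w <- round(params$window_s * fs)
  b0 <- bout$start_index
  len <- bout$end_index - bout$start_index
  k <- floor(len / w)
  empty <- data.frame(second_index = integer(0), start_s = numeric(0), end_s = numeric(0),
                      corr_lr = numeric(0), freeze_ratio_left = numeric(0),
                      freeze_ratio_right = numeric(0), freeze_ratio = numeric(0),
                      potential_by_corr = logical(0), potential_by_ratio = logical(0),
                      is_fog = logical(0))
  if (k < 1) return(empty)
  left <- recording$sensors[[locs[1]]]
  right <- recording$sensors[[locs[2]]]
  lml <- left$gyro[, "ml"]; rml <- right$gyro[, "ml"]
  lap <- left$accel[, "ap"]; rap <- right$accel[, "ap"]

  res <- lapply(seq_len(k) - 1L, function(i) {
    idx <- (b0 + i * w + 1L):(b0 + (i + 1L) * w)
    r <- bilateral_correlation(lml[idx], rml[idx])
    frl <- freezing_ratio(lap[idx], fs, params$low_band, params$high_band)
    frr <- freezing_ratio(rap[idx], fs, params$low_band, params$high_band)
    c(r, frl, frr)
  })
  m <- do.call(rbind, res)
  corr <- m[, 1]; frl <- m[, 2]; frr <- m[, 3]
  combined <- switch(params$foot_combination,
                     max = pmax(frl, frr),
                     mean = (frl + frr) / 2,
                     either = pmax(frl, frr))
  pot_corr <- is.na(corr) | corr < params$corr_threshold
  pot_ratio <- if (params$foot_combination == "either") {
    frl > params$ratio_threshold | frr > params$ratio_threshold
  } else {
    combined > params$ratio_threshold
  }
  data.frame(second_index = seq_len(k) - 1L,
             start_s = (b0 + (seq_len(k) - 1L) * w) / fs,
             end_s = (b0 + seq_len(k) * w) / fs,
             corr_lr = corr,
             freeze_ratio_left = frl, freeze_ratio_right = frr, freeze_ratio = combined,
             potential_by_corr = pot_corr, potential_by_ratio = pot_ratio,
             is_fog = pot_corr & pot_ratio)
}

#' Assemble flagged windows into merged FoG episodes
#'
#' Maximal runs of flagged windows become freezing segments; consecutive
#' segments separated by hesitations of at most `merge_gap_s` of non-freezing
#' time are merged into a single episode whose duration spans from the first
#' segment's start to the last segment's end (hesitation time is included in
#' the duration). Episodes are categorized by [categorize_episode()].
#'
#' @param flags data.frame from [flag_fog_windows()] (one bout, ordered).
#' @param merge_gap_s Maximum merged hesitation (s), default 2.
#' @param bout_id Provenance identifier copied into the output.
#' @return data.frame of disjoint ordered episodes: `start_s`, `end_s`,
#'   `duration_s`, `category`, `n_merged_segments`, `bout_id`.
#' @export
assemble_episodes <- function(flags, merge_gap_s = 2, bout_id = NA_integer_) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0), duration_s = numeric(0),
                      category = factor(character(0), levels = FOG_CATEGORIES),
                      n_merged_segments = integer(0), bout_id = integer(0))
  idx <- which(flags$is_fog)
  if (!length(idx)) return(empty)
  window_s <- if (nrow(flags) >= 1L) flags$end_s[1] - flags$start_s[1] else 1
  # maximal runs of consecutive flagged windows
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  segs <- lapply(seq_len(length(brk) - 1L), function(j) {
    ii <- idx[(brk[j] + 1L):brk[j + 1L]]
    c(first = ii[1L], last = ii[length(ii)])
  })
  # merge segments separated by <= merge_gap_s of non-FoG windows
  episodes <- list()
  cur <- segs[[1L]]
  n_merged <- 1L
  flush <- function(cur, n_merged) {
    start_s <- flags$start_s[cur["first"]]
    end_s <- flags$end_s[cur["last"]]
    data.frame(start_s = start_s, end_s = end_s, duration_s = end_s - start_s,
               category = categorize_episode(end_s - start_s),
               n_merged_segments = n_merged, bout_id = bout_id)
  }
  if (length(segs) > 1L) {
    for (j in 2:length(segs)) {
      gap_s <- (segs[[j]]["first"] - cur["last"] - 1L) * window_s
      if (gap_s <= merge_gap_s) {
        cur["last"] <- segs[[j]]["last"]
        n_merged <- n_merged + 1L
      } else {
        episodes[[length(episodes) + 1L]] <- flush(cur, n_merged)
        cur <- segs[[j]]
        n_merged <- 1L
      }
    }
  }
  episodes[[length(episodes) + 1L]] <- flush(cur, n_merged)
  out <- do.call(rbind, episodes)
  rownames(out) <- NULL
  out
}

#' Categorize an episode duration into the clinical duration bins
#'
#' The clinical questionnaire distinguishes very short (< 1 s), short
#' (2-5 s) and long (> 5 s) freezes; at the detector's 1-s resolution these
#' bins are completed to an exhaustive, order-preserving mapping:
#' single-window episodes (duration < 2 s) are `very_short`, durations of
#' 2-5 s inclusive are `short`, and longer episodes are `long`.
#'
#' @param duration_s Numeric vector of episode durations (s), each >= 1.
#' @return Factor with levels `very_short`, `short`, `long`.
#' @export
categorize_episode <- function(duration_s) {
  if (any(duration_s < 1)) {
    stop("episode durations below the 1-s detector resolution cannot be categorized",
         call. = FALSE)
  }
  out <- ifelse(duration_s < 2, "very_short", ifelse(duration_s <= 5, "short", "long"))
  factor(out, levels = FOG_CATEGORIES)
}

#' Run the full FoG detection chain on a recording
#'
#' Convenience wrapper: 30-min windowing, walking-bout detection and
#' filtering, per-second dual-criterion flagging in every retained bout,
#' episode assembly, and per-window summaries.
#'
#' @param recording An `imu_recording`.
#' @param fparams [fog_params()].
#' @param bparams [bout_params()].
#' @param window_s Analysis window duration in s (default 1800).
#' @param include_very_short Whether very short episodes count towards
#'   freezing time in the summaries (`FALSE` for daily-life mode).
#' @return list with `windows`, `bouts` (retained), `flags` (all bouts,
#'   stacked, with `bout_id`), `episodes`, `summary` (per-window
#'   [summarize_window()] rows).
#' @export
detect_fog <- function(recording, fparams = fog_params(), bparams = bout_params(),
                       window_s = 1800, include_very_short = FALSE) {
  windows <- segment_windows(recording, window_s)
  bouts <- filter_bouts(detect_walking(recording, bparams, windows), bparams$min_bout_s)
  flags <- list(); episodes <- list()
  for (i in seq_len(nrow(bouts))) {
    fl <- flag_fog_windows(recording, bouts[i, ], fparams)
    if (nrow(fl)) fl$bout_id <- bouts$bout_id[i]
    flags[[i]] <- fl
    episodes[[i]] <- assemble_episodes(fl, fparams$merge_gap_s, bouts$bout_id[i])
  }
  flags <- if (length(flags)) do.call(rbind, flags) else NULL
  episodes <- if (length(episodes)) do.call(rbind, episodes) else
    assemble_episodes(data.frame(is_fog = logical(0)))
  summary <- summarize_windows(episodes, bouts, windows, include_very_short)
  list(windows = windows, bouts = bouts, flags = flags,
       episodes = episodes, summary = summary)
}
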