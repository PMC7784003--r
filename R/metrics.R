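# Freezing outcome measures: percentage of walking time spent frozen per
# 30-min window, and weekly aggregates (mean, cumulative sum, coefficient of
# variation, episode-category composition).

#' Summarize freezing within one analysis window
#'
#' Percentage time freezing is the total FoG episode time divided by the
#' total walking (bout) time within the window, times 100. Episodes and bouts
#' are clipped to the window. In daily-life mode very short episodes are
#' excluded from freezing time (they proved unreliable to rate); in
#' laboratory mode set `include_very_short = TRUE`.
#'
#' @param episodes data.frame from [assemble_episodes()].
#' @param bouts data.frame of retained walking bouts.
#' @param window One row of [segment_windows()] output.
#' @param include_very_short Count very short episodes towards freezing time?
#' @return One-row data.frame: `window_id`, `walking_time_s`, `fog_time_s`,
#'   `pct_time_fog` (NA when the window contains no walking), and episode
#'   counts `n_very_short`, `n_short`, `n_long`.
#' @export
summarize_window <- function(episodes, bouts, window, include_very_short = FALSE) {
  ws <- window$start_s; we <- window$end_s
  overlap <- function(s, e) pmax(0, pmin(e, we) - pmax(s, ws))
  walking <- if (nrow(bouts)) sum(overlap(bouts$start_s, bouts$end_s)) else 0
  in_win <- if (nrow(episodes)) overlap(episodes$start_s, episodes$end_s) > 0 else logical(0)
  ep <- episodes[in_win, , drop = FALSE]
  counts <- table(factor(ep$category, levels = FOG_CATEGORIES))
  keep <- if (include_very_short) FOG_CATEGORIES else c("short", "long")
  sel <- ep$category %in% keep
  fog <- if (any(sel)) sum(overlap(ep$start_s[sel], ep$end_s[sel])) else 0
  data.frame(window_id = window$window_id,
             walking_time_s = walking, fog_time_s = fog,
             pct_time_fog = if (walking > 0) 100 * fog / walking else NA_real_,
             n_very_short = as.integer(counts[["very_short"]]),
             n_short = as.integer(counts[["short"]]),
             n_long = as.integer(counts[["long"]]))
}

#' Summarize freezing for every analysis window
#'
#' @param episodes,bouts As in [summarize_window()].
#' @param windows data.frame from [segment_windows()].
#' @param include_very_short Passed through.
#' @return data.frame with one row per window.
#' @export
summarize_windows <- function(episodes, bouts, windows, include_very_short = FALSE) {
  out <- lapply(seq_len(nrow(windows)), function(i) {
    summarize_window(episodes, bouts, windows[i, ], include_very_short)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate per-window freezing summaries over a week
#'
#' Computes the weekly outcome measures: the cumulative sum of per-window
#' freezing percentages, their mean, and their coefficient of variation
#' (sample SD over mean). Windows without walking have undefined percentages
#' and are excluded from all three. Episode-category composition fractions
#' are computed over all episodes of the week.
#'
#' @param summaries data.frame of [summarize_window()] rows (stack several
#'   days to cover a week).
#' @return list of class `weekly_freezing`: `per_window`, `mean_pct`,
#'   `cumsum_pct`, `cv_pct` (NA when fewer than two defined windows or zero
#'   mean), `n_windows_defined`, `episode_counts`, `composition`.
#' @export
summarize_week <- function(summaries) {
  pct <- summaries$pct_time_fog
  defined <- !is.na(pct)
  if (!any(defined)) {
    stop("no analysis window contains walking; weekly freezing outcomes are undefined",
         call. = FALSE)
  }
  p <- pct[defined]
  mean_pct <- mean(p)
  cumsum_pct <- sum(p)
  cv_pct <- if (length(p) >= 2 && mean_pct > 0) stats::sd(p) / mean_pct else NA_real_
  counts <- c(very_short = sum(summaries$n_very_short),
              short = sum(summaries$n_short),
              long = sum(summaries$n_long))
  total <- sum(counts)
  composition <- if (total > 0) counts / total else counts * NA_real_
  structure(list(per_window = summaries, mean_pct = mean_pct, cumsum_pct = cumsum_pct,
                 cv_pct = cv_pct, n_windows_defined = length(p),
                 episode_counts = counts, composition = composition),
            class = "weekly_freezing")
}

#' @export
print.weekly_freezing <- function(x, ...) {
  cat(sprintf("<weekly_freezing> %d window(s) with walking\n", x$n_windows_defined))
  cat(sprintf("  mean %% time freezing: %.3f | cumulative: %.3f | CV: %s\n",
              x$mean_pct, x$cumsum_pct,
              if (is.na(x$cv_pct)) "NA" else sprintf("%.3f", x$cv_pct)))
  cat("  episodes:", paste(sprintf("%s=%d", names(x$episode_counts), x$episode_counts),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Classify a subject as freezer or non-freezer from weekly freezing burden
#'
#' The subject-level score is the mean fraction of walking time spent frozen
#' (mean weekly percentage / 100); a subject scoring strictly above the
#' threshold is classified a freezer. The default threshold 0.09 is the
#' published operating point against clinical rater 1.
#'
#' @param weekly A `weekly_freezing` object (or its `mean_pct` value).
#' @param threshold Decision threshold on the score (fraction of walking
#'   time).
#' @return list with `score` and logical `is_freezer`.
#' @export
classify_freezer <- function(weekly, threshold = 0.09) {
  mean_pct <- if (inherits(weekly, "weekly_freezing")) weekly$mean_pct else as.numeric(weekly)
  score <- mean_pct / 100
  list(score = score, is_freezer = score > threshold)
}
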