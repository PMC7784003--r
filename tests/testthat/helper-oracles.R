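# Independent oracles used across the suite. These deliberately use naive,
# explicit computations (loops, direct definitions) so that they share no
# code path with the package implementation they check.

# band energy by brute-force DFT summation (O(n^2), definition-level)
dft_band_energy <- function(x, fs, lo, hi) {
  n <- length(x)
  x <- x - sum(x) / n
  e <- 0
  for (k in 1:(n %/% 2)) {
    f <- k * fs / n
    if (f > lo && f <= hi) {
      re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
      im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
      e <- e + re^2 + im^2
    }
  }
  e
}

# product-moment correlation from the raw definition
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# merge flagged seconds into episodes by linear scan: a flagged second joins
# the current episode when the hesitation since the previous flagged second
# is at most `gap`, otherwise it opens a new episode
merge_oracle <- function(flagged_secs, gap) {
  if (!length(flagged_secs)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  s <- sort(flagged_secs)
  starts <- s[1]; ends <- s[1] + 1
  for (x in s[-1]) {
    if (x - ends[length(ends)] <= gap) {
      ends[length(ends)] <- x + 1
    } else {
      starts <- c(starts, x)
      ends <- c(ends, x + 1)
    }
  }
  data.frame(start = starts, end = ends)
}

# ICC(2,1) from explicit cell-level ANOVA sums
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  msr <- 0
  for (i in 1:n) msr <- msr + (mean(m[i, ]) - gm)^2
  msr <- msr * k / (n - 1)
  msc <- 0
  for (j in 1:k) msc <- msc + (mean(m[, j]) - gm)^2
  msc <- msc * n / (k - 1)
  sse <- 0
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + gm)^2
  }
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# AUC as the normalized Mann-Whitney U statistic (ties count 1/2)
auc_mannwhitney <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  u <- 0
  for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
  u / (length(pos) * length(neg))
}

# flags table for assemble_episodes() from a set of flagged second indices
make_flags <- function(flagged_secs, n_secs, offset_s = 0) {
  sec <- seq_len(n_secs) - 1L
  data.frame(second_index = sec,
             start_s = offset_s + sec, end_s = offset_s + sec + 1,
             is_fog = sec %in% flagged_secs)
}

# detect + summarize one multi-day synthetic subject
analyze_subject <- function(subj, ...) {
  sums <- do.call(rbind, lapply(subj$days, function(d) detect_fog(d$recording, ...)$summary))
  sums$window_id <- seq_len(nrow(sums))
  summarize_week(sums)
}
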