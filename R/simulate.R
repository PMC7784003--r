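# Labelled synthetic multi-sensor recordings.
#
# The generator targets the statistical structure the detector relies on --
# band energies and bilateral correlation -- not biomechanically faithful
# gait. Walking drives both feet with a common locomotor-band waveform
# (correlation near 1); scheduled FoG intervals suppress the locomotor
# component and inject band-limited trembling with independent left/right
# phase (correlation near 0, accelerometer energy concentrated in the freeze
# band); rest is a noise floor plus low-frequency postural sway. Amplitudes
# are expressed in accelerometer units (m/s^2); gyroscope channels use a
# fixed scale of 50 (deg/s) per (m/s^2)-unit so that one amplitude set drives
# all channels coherently.

GYRO_SCALE <- 50  # deg/s of foot angular rate per unit (m/s^2) of amplitude

#' Define a synthetic recording scenario
#'
#' @param total_duration_s Total recording duration (s).
#' @param walking_segments List of `c(start, end)` walking intervals (s,
#'   half-open); everything else is rest.
#' @param fog_schedule List of `c(start, end)` freezing intervals (s), each
#'   contained in a walking segment.
#' @param turn_schedule data.frame with columns `start_s`, `angle_deg`,
#'   `duration_s` and optionally `direction` (`"left"`/`"right"`), or NULL.
#' @param stride_freq Stride frequency (Hz) of the locomotor waveform
#'   (default 1.0; harmonics are kept within the 0.5-3 Hz locomotor band).
#' @param tremor_freq Center of the trembling activity (Hz, default 5).
#' @param tremor_band Band (Hz) of the trembling noise bursts (default
#'   3.5-9.5 Hz, inside the detector's 3-10 Hz freeze band so that windowing
#'   leakage into the locomotor band stays negligible).
#' @param tremor_mode `"noise"` (band-passed noise, default; avoids FFT
#'   bin-alignment artifacts) or `"tone"` (pure sinusoid at `tremor_freq`,
#'   for analytic tests).
#' @param tremor_bilateral_corr Correlation of left and right trembling in
#'   \[0, 1\] (default 0: bilaterally independent).
#' @param locomotor_amp Locomotor waveform amplitude (m/s^2 RMS, default 2).
#' @param tremor_amp Trembling amplitude during FoG (m/s^2 RMS, default 3).
#' @param noise_sd Additive white sensor noise SD (m/s^2; gyro channels get
#'   `GYRO_SCALE` times this in deg/s). Default 0.1.
#' @param sway_amp Low-frequency (0.5-2.5 Hz) postural sway amplitude always
#'   present on the accelerometers (m/s^2 RMS, default `0.15 * locomotor_amp`).
#' @param fog_suppression Residual fraction of the locomotor amplitude during
#'   freezing (default 0.1).
#' @param sensors Locations to synthesize; must include both feet and lumbar.
#' @param sampling_rate Hz, default 128.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param subject_id Subject label.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(total_duration_s, walking_segments = list(),
                         fog_schedule = list(), turn_schedule = NULL,
                         stride_freq = 1.0, tremor_freq = 5.0, tremor_band = c(3.5, 9.5),
                         tremor_mode = c("noise", "tone"), tremor_bilateral_corr = 0,
                         locomotor_amp = 2, tremor_amp = 3, noise_sd = 0.1,
                         sway_amp = 0.15 * locomotor_amp, fog_suppression = 0.1,
                         sensors = c("left_foot", "right_foot", "lumbar"),
                         sampling_rate = 128, seed = 1L, subject_id = "sim") {
  tremor_mode <- match.arg(tremor_mode)
  as_seg <- function(x) {
    if (!length(x)) return(matrix(numeric(0), ncol = 2))
    m <- do.call(rbind, lapply(x, function(s) as.numeric(s[1:2])))
    if (any(m[, 2] <= m[, 1])) stop("segments must have end > start", call. = FALSE)
    m[order(m[, 1]), , drop = FALSE]
  }
  walk <- as_seg(walking_segments)
  fog <- as_seg(fog_schedule)
  check_disjoint <- function(m, what) {
    if (nrow(m) > 1L && any(m[-1L, 1] < m[-nrow(m), 2])) {
      stop(sprintf("%s overlap", what), call. = FALSE)
    }
  }
  check_disjoint(walk, "walking segments")
  check_disjoint(fog, "fog intervals")
  if (nrow(walk) && any(walk[, 2] > total_duration_s)) {
    stop("walking segments exceed the recording duration", call. = FALSE)
  }
  for (i in seq_len(nrow(fog))) {
    inside <- any(fog[i, 1] >= walk[, 1] & fog[i, 2] <= walk[, 2])
    if (!inside) {
      stop(sprintf("fog interval [%g, %g) lies outside every walking segment",
                   fog[i, 1], fog[i, 2]), call. = FALSE)
    }
  }
  if (!all(c("left_foot", "right_foot", "lumbar") %in% sensors)) {
    stop("sensors must include left_foot, right_foot and lumbar", call. = FALSE)
  }
  if (tremor_bilateral_corr < 0 || tremor_bilateral_corr > 1) {
    stop("tremor_bilateral_corr must lie in [0, 1]", call. = FALSE)
  }
  structure(list(total_duration_s = total_duration_s, walking = walk, fog = fog,
                 turns = turn_schedule, stride_freq = stride_freq,
                 tremor_freq = tremor_freq, tremor_band = as.numeric(tremor_band),
                 tremor_mode = tremor_mode, tremor_bilateral_corr = tremor_bilateral_corr,
                 locomotor_amp = locomotor_amp, tremor_amp = tremor_amp,
                 noise_sd = noise_sd, sway_amp = sway_amp,
                 fog_suppression = fog_suppression, sensors = sensors,
                 sampling_rate = sampling_rate, seed = as.integer(seed),
                 subject_id = subject_id),
            class = "sim_scenario")
}

in_segments <- function(t, segs) {
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(segs))) out <- out | (t >= segs[i, 1] & t < segs[i, 2])
  out
}

# unit-RMS band-limited Gaussian noise, synthesized in the frequency domain
# so that the spectrum is exactly zero outside [band[1], band[2]] Hz (a filter
# skirt would leak tremor energy into the locomotor band and corrupt the
# freeze ratio by construction)
band_noise <- function(n, fs, band) {
  f <- (seq_len(n) - 1) * fs / n
  sel <- which(f >= band[1] & f <= band[2] & f <= fs / 2 & f > 0)
  spec <- complex(n)
  spec[sel] <- complex(real = stats::rnorm(length(sel)),
                       imaginary = stats::rnorm(length(sel)))
  mirror <- n + 2L - sel
  mirror_ok <- mirror <= n & mirror != sel
  spec[mirror[mirror_ok]] <- Conj(spec[sel][mirror_ok])
  x <- Re(stats::fft(spec, inverse = TRUE))
  x / stats::sd(x)
}

# unit-RMS harmonic series locked to the locomotor band
harmonic_waveform <- function(t, f0, amps = c(1, 0.5, 0.25), fmax = 3) {
  y <- 0
  for (h in seq_along(amps)) {
    fh <- h * f0
    if (fh > fmax) break
    y <- y + amps[h] * sin(2 * pi * fh * t + stats::runif(1, 0, 2 * pi))
  }
  y / stats::sd(y)
}

#' Generate a labelled synthetic recording
#'
#' @param scenario A [sim_scenario()].
#' @return list with `recording` (an `imu_recording`) and `truth` (list with
#'   per-second `labels` — factor rest/walk/fog — plus `fog_episodes`,
#'   `walking` and `turns` tables).
#' @export
generate_recording <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  fs <- sc$sampling_rate
  n <- round(sc$total_duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  set.seed(sc$seed)

  walk_mask <- in_segments(t, sc$walking)            # lumbar activity incl. FoG
  fog_mask <- in_segments(t, sc$fog)
  gait_mask <- walk_mask & !fog_mask                 # clean-gait samples
  e_walk <- as.numeric(gait_mask) + sc$fog_suppression * as.numeric(fog_mask)
  e_fog <- as.numeric(fog_mask)

  w_ml <- harmonic_waveform(t, sc$stride_freq)               # common foot ML gyro waveform
  v_ap <- harmonic_waveform(t, sc$stride_freq, c(1, 0.4), 3) # common AP accel waveform
  v_v <- harmonic_waveform(t, sc$stride_freq, c(0.6, 1), 3)  # vertical accel waveform

  if (sc$tremor_mode == "noise") {
    common <- band_noise(n, fs, sc$tremor_band)
    trem <- list(left = sqrt(sc$tremor_bilateral_corr) * common +
                   sqrt(1 - sc$tremor_bilateral_corr) * band_noise(n, fs, sc$tremor_band),
                 right = sqrt(sc$tremor_bilateral_corr) * common +
                   sqrt(1 - sc$tremor_bilateral_corr) * band_noise(n, fs, sc$tremor_band))
  } else {
    ph <- if (sc$tremor_bilateral_corr >= 1) rep(stats::runif(1, 0, 2 * pi), 2)
          else stats::runif(2, 0, 2 * pi)
    trem <- list(left = sqrt(2) * sin(2 * pi * sc$tremor_freq * t + ph[1]),
                 right = sqrt(2) * sin(2 * pi * sc$tremor_freq * t + ph[2]))
  }

  gy_amp <- GYRO_SCALE * sc$locomotor_amp
  gy_trem <- GYRO_SCALE * sc$tremor_amp
  gy_noise <- GYRO_SCALE * sc$noise_sd
  sway <- function() sc$sway_amp * band_noise(n, fs, c(0.5, 2.5))
  wn <- function(sd) stats::rnorm(n, sd = sd)

  make_leg <- function(side, scale = 1) {
    tr <- trem[[side]]
    # gyro trembling carries an extra independent broadband component (jerky,
    # non-rhythmic leg movement); pure narrowband trembling over 1 s has so
    # few degrees of freedom that chance bilateral correlations become common
    tr_gyro <- sqrt(0.6) * tr + sqrt(0.4) * stats::rnorm(n)
    gml <- scale * (gy_amp * w_ml * e_walk + gy_trem * tr_gyro * e_fog) + wn(gy_noise)
    gap <- scale * 0.3 * gy_amp * w_ml * e_walk + wn(gy_noise)
    gv <- scale * 0.3 * gy_amp * w_ml * e_walk + wn(gy_noise)
    aap <- scale * (sc$locomotor_amp * v_ap * e_walk + sc$tremor_amp * tr * e_fog) +
      sway() + wn(sc$noise_sd)
    aml <- scale * 0.5 * sc$locomotor_amp * v_ap * e_walk + sway() + wn(sc$noise_sd)
    av <- 9.81 + scale * 0.6 * sc$locomotor_amp * v_v * e_walk + sway() + wn(sc$noise_sd)
    sensor_stream(cbind(ap = aap, ml = aml, v = av),
                  cbind(ap = gap, ml = gml, v = gv))
  }

  # lumbar: locomotor-band trunk activity throughout walking (freezing happens
  # within a bout, so the bout gate must stay open), yaw pulses for turns
  yaw <- numeric(n)
  truth_turns <- data.frame(start_s = numeric(0), end_s = numeric(0),
                            angle_deg = numeric(0), duration_s = numeric(0),
                            direction = character(0))
  if (!is.null(sc$turns) && nrow(sc$turns)) {
    for (i in seq_len(nrow(sc$turns))) {
      tr <- sc$turns[i, ]
      dir <- if (!is.null(tr$direction)) tr$direction else "left"
      sgn <- if (identical(dir, "right")) -1 else 1
      amp <- 2 * tr$angle_deg / tr$duration_s
      sel <- t >= tr$start_s & t < tr$start_s + tr$duration_s
      tau <- (t[sel] - tr$start_s) / tr$duration_s
      yaw[sel] <- yaw[sel] + sgn * amp * (1 - cos(2 * pi * tau)) / 2
      truth_turns <- rbind(truth_turns,
                           data.frame(start_s = tr$start_s,
                                      end_s = tr$start_s + tr$duration_s,
                                      angle_deg = tr$angle_deg,
                                      duration_s = tr$duration_s, direction = dir))
    }
  }
  lum_gap <- 0.3 * gy_amp * w_ml * as.numeric(walk_mask) + wn(gy_noise)
  lum_gml <- 0.3 * gy_amp * harmonic_waveform(t, sc$stride_freq) * as.numeric(walk_mask) +
    wn(gy_noise)
  lum_gv <- yaw + wn(0.2 * gy_noise)  # trunk yaw is far quieter than foot swing
  lum_aap <- 0.3 * sc$locomotor_amp * v_ap * as.numeric(walk_mask) + sway() + wn(sc$noise_sd)
  lum_aml <- 0.3 * sc$locomotor_amp * v_ap * as.numeric(walk_mask) + sway() + wn(sc$noise_sd)
  lum_av <- 9.81 + 0.4 * sc$locomotor_amp * v_v * as.numeric(walk_mask) + sway() +
    wn(sc$noise_sd)

  sensors <- list()
  for (loc in sc$sensors) {
    sensors[[loc]] <- switch(loc,
      left_foot = make_leg("left"),
      right_foot = make_leg("right"),
      left_shin = make_leg("left", scale = 0.8),
      right_shin = make_leg("right", scale = 0.8),
      lumbar = sensor_stream(cbind(ap = lum_aap, ml = lum_aml, v = lum_av),
                             cbind(ap = lum_gap, ml = lum_gml, v = lum_gv)))
  }
  rec <- imu_recording(sensors, sampling_rate = fs, subject_id = sc$subject_id,
                       metadata = list(synthetic = TRUE, seed = sc$seed))

  secs <- seq_len(floor(sc$total_duration_s)) - 1L
  mid <- secs + 0.5
  labels <- ifelse(in_segments(mid, sc$fog), "fog",
                   ifelse(in_segments(mid, sc$walking), "walk", "rest"))
  truth <- list(
    labels = data.frame(second = secs,
                        label = factor(labels, levels = c("rest", "walk", "fog"))),
    fog_episodes = if (nrow(sc$fog)) {
      data.frame(start_s = sc$fog[, 1], end_s = sc$fog[, 2],
                 duration_s = sc$fog[, 2] - sc$fog[, 1])
    } else data.frame(start_s = numeric(0), end_s = numeric(0), duration_s = numeric(0)),
    walking = if (nrow(sc$walking)) {
      data.frame(start_s = sc$walking[, 1], end_s = sc$walking[, 2])
    } else data.frame(start_s = numeric(0), end_s = numeric(0)),
    turns = truth_turns
  )
  list(recording = rec, truth = truth)
}

#' Schedule FoG episodes inside walking segments to a freezing-time target
#'
#' Greedy randomized placement: episode durations are drawn (10-20 s, with
#' the last clipped to the remaining budget) and laid into the walking
#' segments with margins of at least 2 s from the segment borders and
#' inter-episode gaps wide enough that detected episodes cannot merge.
#'
#' @param walking_segments List of `c(start, end)` intervals (s).
#' @param target_s Total freezing time to schedule (s); values below 6 s
#'   produce an empty schedule.
#' @return List of `c(start, end)` fog intervals.
#' @export
schedule_fog <- function(walking_segments, target_s) {
  schedule <- list()
  remaining <- round(target_s)
  for (seg in walking_segments) {
    if (remaining < 6) break
    cursor <- floor(seg[1]) + 2 + sample(0:3, 1)
    seg_end <- floor(seg[2]) - 2
    repeat {
      if (remaining < 6) break
      d <- min(sample(10:20, 1), remaining)
      if (remaining - d < 6) d <- min(remaining, 25)
      if (cursor + d > seg_end) break
      schedule[[length(schedule) + 1L]] <- c(cursor, cursor + d)
      remaining <- remaining - d
      cursor <- cursor + d + sample(5:12, 1)
    }
  }
  schedule
}

#' Generate a synthetic multi-day cohort of freezers and non-freezers
#'
#' Emulates a week-long home-monitoring design at reduced scale: every
#' subject contributes several daily sessions of walking and rest; freezers
#' receive a per-subject freezing fraction (fraction of walking time spent
#' frozen) drawn from a Beta distribution (or fixed per subject), and
#' episodes are scheduled accordingly; non-freezers freeze not at all.
#'
#' @param n_freezers,n_nonfreezers Group sizes.
#' @param week_spec List: `n_days` (default 3), `day_duration_s` (default
#'   600), `walking_segments` per day (default two ~200-s segments),
#'   `fog_fraction_mean` / `fog_fraction_kappa` of the Beta draw (defaults
#'   0.15 / 40), or `fog_fractions`, an explicit per-freezer vector
#'   overriding the Beta draw. Remaining [sim_scenario()] fields can be
#'   overridden via `scenario_args`.
#' @param seed Master integer seed; all per-day scenario seeds derive from it.
#' @return List of subjects; each has `subject_id`, `group`, `fog_fraction`
#'   (scheduled), and `days` — a list of `generate_recording()` results.
#' @export
generate_cohort <- function(n_freezers, n_nonfreezers, week_spec = list(), seed = 1L) {
  spec <- list(
    n_days = 3L, day_duration_s = 600,
    walking_segments = list(c(30, 230), c(330, 530)),
    fog_fraction_mean = 0.15, fog_fraction_kappa = 40,
    fog_fractions = NULL, scenario_args = list()
  )
  # plain (non-recursive) override: segment lists are positional, not named
  for (nm in names(week_spec)) spec[[nm]] <- week_spec[[nm]]
  set.seed(seed)
  n_total <- n_freezers + n_nonfreezers
  day_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_total * spec$n_days),
                      nrow = n_total)
  fracs <- if (!is.null(spec$fog_fractions)) {
    rep_len(spec$fog_fractions, n_freezers)
  } else if (n_freezers > 0) {
    stats::rbeta(n_freezers, spec$fog_fraction_mean * spec$fog_fraction_kappa,
                 (1 - spec$fog_fraction_mean) * spec$fog_fraction_kappa)
  } else numeric(0)
  walking_total <- sum(vapply(spec$walking_segments, function(s) s[2] - s[1], numeric(1)))
  subjects <- list()
  for (i in seq_len(n_total)) {
    freezer <- i <= n_freezers
    frac <- if (freezer) fracs[i] else 0
    days <- list()
    scheduled <- 0
    for (d in seq_len(spec$n_days)) {
      fog <- if (freezer) schedule_fog(spec$walking_segments, frac * walking_total) else list()
      scheduled <- scheduled + sum(vapply(fog, function(x) x[2] - x[1], numeric(1)))
      args <- list(
        total_duration_s = spec$day_duration_s,
        walking_segments = spec$walking_segments,
        fog_schedule = fog,
        seed = day_seeds[i, d],
        subject_id = sprintf("subj%02d", i)
      )
      for (nm in names(spec$scenario_args)) args[[nm]] <- spec$scenario_args[[nm]]
      days[[d]] <- generate_recording(do.call(sim_scenario, args))
    }
    subjects[[i]] <- list(
      subject_id = sprintf("subj%02d", i),
      group = if (freezer) "freezer" else "non_freezer",
      fog_fraction = frac,
      scheduled_fog_fraction = scheduled / (spec$n_days * walking_total),
      days = days
    )
  }
  subjects
}
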