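# Data model for synchronized inertial recordings, text I/O, and windowing.
#
# Axis convention used throughout: every accelerometer / gyroscope array is an
# N x 3 matrix with columns "ap" (antero-posterior), "ml" (medio-lateral) and
# "v" (vertical) in the sensor frame. Accelerations are in m/s^2, angular
# rates in deg/s. The on-disk manifest declares per-file units and axis order
# so that heterogeneous exports can be normalized at load time.

SENSOR_LOCATIONS <- c("left_foot", "right_foot", "left_shin", "right_shin", "lumbar")
AXES <- c("ap", "ml", "v")

#' Construct a single sensor stream
#'
#' A sensor stream holds the tri-axial accelerometer and gyroscope signals of
#' one body-worn inertial unit, already converted to canonical units and axis
#' order.
#'
#' @param accel Numeric N x 3 matrix of accelerations in m/s^2. Columns are
#'   antero-posterior, medio-lateral, vertical (named `ap`, `ml`, `v`; unnamed
#'   matrices are assumed to already be in that order).
#' @param gyro Numeric N x 3 matrix of angular velocities in deg/s about the
#'   same three axes.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(accel, gyro) {
  accel <- as_axis_matrix(accel, "accel")
  gyro <- as_axis_matrix(gyro, "gyro")
  if (nrow(accel) != nrow(gyro)) {
    stop(sprintf("accel has %d samples but gyro has %d; streams must be synchronized",
                 nrow(accel), nrow(gyro)), call. = FALSE)
  }
  if (nrow(accel) < 1L) stop("sensor stream must contain at least one sample", call. = FALSE)
  if (anyNA(accel) || anyNA(gyro)) {
    stop("sensor stream contains NA/NaN values; gaps must be split into separate recordings",
         call. = FALSE)
  }
  structure(list(accel = accel, gyro = gyro), class = "sensor_stream")
}

as_axis_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 3L) stop(sprintf("%s must have 3 columns (ap, ml, v), got %d", what, ncol(m)),
                          call. = FALSE)
  if (!is.numeric(m)) stop(sprintf("%s must be numeric", what), call. = FALSE)
  if (!is.null(colnames(m))) {
    if (!all(AXES %in% colnames(m))) {
      stop(sprintf("%s columns must be named %s (got: %s)", what,
                   paste(AXES, collapse = ", "), paste(colnames(m), collapse = ", ")),
           call. = FALSE)
    }
    m <- m[, AXES, drop = FALSE]
  } else {
    colnames(m) <- AXES
  }
  storage.mode(m) <- "double"
  m
}

#' Construct a synchronized multi-sensor recording
#'
#' @param sensors Named list of [sensor_stream()] objects. Names must be among
#'   `left_foot`, `right_foot`, `left_shin`, `right_shin`, `lumbar`.
#' @param sampling_rate Sampling rate in Hz shared by all streams (default 128).
#' @param start_time Numeric offset (s) of the first sample; 0 by default.
#' @param subject_id Opaque subject identifier.
#' @param metadata Free-form named list (clinical scores, group label, ...).
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(sensors, sampling_rate = 128, start_time = 0,
                          subject_id = "subject", metadata = list()) {
  if (!is.list(sensors) || is.null(names(sensors)) || any(names(sensors) == "")) {
    stop("`sensors` must be a named list of sensor streams", call. = FALSE)
  }
  bad <- setdiff(names(sensors), SENSOR_LOCATIONS)
  if (length(bad)) {
    stop(sprintf("unknown sensor location(s): %s (expected among: %s)",
                 paste(bad, collapse = ", "), paste(SENSOR_LOCATIONS, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(vapply(sensors, inherits, logical(1), "sensor_stream"))) {
    stop("every element of `sensors` must be a sensor_stream", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive scalar (Hz)", call. = FALSE)
  }
  ns <- vapply(sensors, function(s) nrow(s$accel), integer(1))
  if (length(unique(ns)) != 1L) {
    stop(sprintf("sensors are not synchronized; sample counts differ: %s",
                 paste(sprintf("%s=%d", names(ns), ns), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(sensors = sensors, sampling_rate = sampling_rate,
                 start_time = start_time, subject_id = subject_id,
                 metadata = metadata),
            class = "imu_recording")
}

#' Number of samples per stream in a recording
#' @param recording An `imu_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(recording) {
  stopifnot(inherits(recording, "imu_recording"))
  nrow(recording$sensors[[1L]]$accel)
}

#' Recording duration in seconds
#' @param recording An `imu_recording`.
#' @return Duration in s.
#' @export
duration_s <- function(recording) n_samples(recording) / recording$sampling_rate

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject '%s': %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, n_samples(x), x$sampling_rate, duration_s(x)))
  cat("  sensors:", paste(names(x$sensors), collapse = ", "), "\n")
  invisible(x)
}

# Resolve the pair of sensor locations used by the FoG detector for a given
# placement, or fail with an informative error.
placement_locations <- function(placement = c("feet", "shins")) {
  placement <- match.arg(placement)
  if (placement == "feet") c("left_foot", "right_foot") else c("left_shin", "right_shin")
}

require_sensors <- function(recording, locations) {
  missing <- setdiff(locations, names(recording$sensors))
  if (length(missing)) {
    stop(sprintf("recording '%s' lacks required sensor location(s): %s",
                 recording$subject_id, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Split a recording into consecutive fixed-duration analysis windows
#'
#' Daily-life outcomes are aggregated over 30-minute windows; this returns the
#' tiling of the recording into such windows. Indices are 0-based and
#' half-open, so the union of all windows is exactly `[0, n_samples)` with no
#' overlap. A final window shorter than `window_s` is kept and flagged partial.
#'
#' @param recording An `imu_recording` (or an integer sample count).
#' @param window_s Window duration in seconds (default 1800 s = 30 min).
#' @param sampling_rate Required when `recording` is a plain sample count.
#' @return data.frame with columns `window_id`, `start_index`, `end_index`
#'   (samples, half-open), `start_s`, `end_s`, `partial`.
#' @export
segment_windows <- function(recording, window_s = 1800, sampling_rate = NULL) {
  if (inherits(recording, "imu_recording")) {
    n <- n_samples(recording)
    fs <- recording$sampling_rate
  } else {
    n <- as.integer(recording)
    fs <- sampling_rate
    if (is.null(fs)) stop("`sampling_rate` must be given with a plain sample count", call. = FALSE)
  }
  if (window_s <= 0) stop("`window_s` must be positive", call. = FALSE)
  w <- round(window_s * fs)
  starts <- seq.int(0L, n - 1L, by = w)
  ends <- pmin(starts + w, n)
  data.frame(window_id = seq_along(starts),
             start_index = starts, end_index = ends,
             start_s = starts / fs, end_s = ends / fs,
             partial = (ends - starts) < w)
}

#' Write a recording as a manifest plus one CSV per sensor
#'
#' The on-disk dialect is deliberately plain: a YAML manifest
#' (`manifest.yaml`) declaring subject, sampling rate, and for every sensor
#' the file name, units and axis order, plus one CSV per sensor with columns
#' `t, ax, ay, az, gx, gy, gz`.
#'
#' @param recording An `imu_recording`.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "imu_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- n_samples(recording)
  t <- (seq_len(n) - 1L) / recording$sampling_rate
  manifest <- list(
    subject_id = recording$subject_id,
    sampling_rate = recording$sampling_rate,
    start_time = recording$start_time,
    metadata = recording$metadata,
    sensors = list()
  )
  for (loc in names(recording$sensors)) {
    s <- recording$sensors[[loc]]
    file <- paste0(loc, ".csv")
    df <- data.frame(t = t,
                     ax = s$accel[, "ap"], ay = s$accel[, "ml"], az = s$accel[, "v"],
                     gx = s$gyro[, "ap"], gy = s$gyro[, "ml"], gz = s$gyro[, "v"])
    utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     file.path(dir, file), row.names = FALSE, quote = FALSE)
    manifest$sensors[[loc]] <- list(file = file,
                                    accel_units = "m/s^2",
                                    gyro_units = "deg/s",
                                    axis_order = AXES)
  }
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Load a recording from a manifest plus per-sensor CSV files
#'
#' Reads the manifest, loads every declared sensor file, converts units to
#' m/s^2 and deg/s, reorders axes to the canonical (ap, ml, v) convention and
#' validates synchronization. If the declared sampling rate differs from
#' `target_rate`, all channels are resampled by polyphase filtering (the
#' detector thresholds assume 128 Hz).
#'
#' @param manifest_path Path to the YAML manifest written by
#'   [write_recording()] (or hand-authored in the same dialect).
#' @param target_rate Analysis sampling rate in Hz (default 128).
#' @return An `imu_recording`. The original sampling rate, if resampled, is
#'   recorded in `metadata$original_sampling_rate`.
#' @export
load_recording <- function(manifest_path, target_rate = 128) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: %s", manifest_path), call. = FALSE)
  }
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$sensors) || !length(man$sensors)) {
    stop("manifest declares no sensors", call. = FALSE)
  }
  fs <- man$sampling_rate
  if (is.null(fs)) stop("manifest lacks `sampling_rate`", call. = FALSE)
  base <- dirname(manifest_path)
  cols <- c("ax", "ay", "az", "gx", "gy", "gz")
  sensors <- list()
  lens <- integer(0)
  for (loc in names(man$sensors)) {
    decl <- man$sensors[[loc]]
    path <- file.path(base, decl$file)
    if (!file.exists(path)) stop(sprintf("sensor '%s': file not found: %s", loc, path), call. = FALSE)
    df <- utils::read.csv(path)
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      stop(sprintf("sensor '%s': missing column(s) %s in %s", loc,
                   paste(missing, collapse = ", "), decl$file), call. = FALSE)
    }
    accel <- as.matrix(df[, c("ax", "ay", "az")])
    gyro <- as.matrix(df[, c("gx", "gy", "gz")])
    accel_units <- decl$accel_units %||% "m/s^2"
    gyro_units <- decl$gyro_units %||% "deg/s"
    accel <- accel * switch(accel_units, "m/s^2" = 1, "g" = 9.80665,
                            stop(sprintf("sensor '%s': unknown accel_units '%s'", loc, accel_units),
                                 call. = FALSE))
    gyro <- gyro * switch(gyro_units, "deg/s" = 1, "rad/s" = 180 / pi,
                          stop(sprintf("sensor '%s': unknown gyro_units '%s'", loc, gyro_units),
                               call. = FALSE))
    order <- unlist(decl$axis_order %||% AXES)
    if (!setequal(order, AXES) || length(order) != 3L) {
      stop(sprintf("sensor '%s': axis_order must be a permutation of ap, ml, v", loc), call. = FALSE)
    }
    colnames(accel) <- order
    colnames(gyro) <- order
    if (anyNA(accel) || anyNA(gyro)) {
      stop(sprintf("sensor '%s': non-numeric or missing values in %s", loc, decl$file), call. = FALSE)
    }
    sensors[[loc]] <- sensor_stream(accel, gyro)
    lens[loc] <- nrow(accel)
  }
  if (length(unique(lens)) != 1L) {
    stop(sprintf("sensor files are not synchronized; sample counts differ: %s",
                 paste(sprintf("%s=%d", names(lens), lens), collapse = ", ")), call. = FALSE)
  }
  metadata <- man$metadata %||% list()
  if (abs(fs - target_rate) > 1e-9) {
    sensors <- lapply(sensors, resample_stream, from = fs, to = target_rate)
    metadata$original_sampling_rate <- fs
    fs <- target_rate
  }
  imu_recording(sensors, sampling_rate = fs,
                start_time = man$start_time %||% 0,
                subject_id = man$subject_id %||% "subject",
                metadata = metadata)
}

resample_stream <- function(s, from, to) {
  rat <- rational_approx(to / from)
  res <- function(m) apply(m, 2, function(x) signal::resample(x, p = rat[1], q = rat[2]))
  a <- res(s$accel); g <- res(s$gyro)
  colnames(a) <- AXES; colnames(g) <- AXES
  sensor_stream(a, g)
}

rational_approx <- function(x, max_den = 1024L) {
  # best rational p/q with q <= max_den (continued fractions)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(p1, q1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
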