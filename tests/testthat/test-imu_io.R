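test_that("segment_windows tiles recordings into half-open 30-min windows", {
  # 2 h at 128 Hz -> 4 full windows
  w <- segment_windows(2 * 3600 * 128, sampling_rate = 128)
  expect_equal(nrow(w), 4)
  expect_false(any(w$partial))
  # 2500 s -> [0, 1800) and [1800, 2500), second partial
  w <- segment_windows(2500 * 128, sampling_rate = 128)
  expect_equal(w$start_s, c(0, 1800))
  expect_equal(w$end_s, c(1800, 2500))
  expect_equal(w$partial, c(FALSE, TRUE))
  # 10 s -> one partial window
  w <- segment_windows(10 * 128, sampling_rate = 128)
  expect_equal(nrow(w), 1)
  expect_true(w$partial)
  # tiling property: union of half-open ranges is [0, N), no overlap
  for (n in c(1, 100, 230400, 230401, 459173)) {
    w <- segment_windows(n, sampling_rate = 128)
    expect_equal(w$start_index[1], 0)
    expect_equal(w$end_index[nrow(w)], n)
    if (nrow(w) > 1) expect_equal(w$start_index[-1], w$end_index[-nrow(w)])
  }
})

test_that("recordings round-trip through the manifest + CSV dialect", {
  set.seed(1)
  n <- 128 * 5
  mk <- function() sensor_stream(matrix(rnorm(3 * n), ncol = 3),
                                 matrix(rnorm(3 * n, sd = 50), ncol = 3))
  rec <- imu_recording(list(left_foot = mk(), right_foot = mk(), lumbar = mk()),
                       subject_id = "rt01",
                       metadata = list(group = "freezer", nfogq = 17))
  dir <- withr::local_tempdir()
  path <- write_recording(rec, dir)
  back <- load_recording(path)
  expect_equal(back$subject_id, "rt01")
  expect_equal(back$metadata$group, "freezer")
  expect_equal(back$metadata$nfogq, 17)
  expect_equal(back$sampling_rate, 128)
  for (loc in names(rec$sensors)) {
    expect_lt(max(abs(back$sensors[[loc]]$accel - rec$sensors[[loc]]$accel)), 1e-9)
    expect_lt(max(abs(back$sensors[[loc]]$gyro - rec$sensors[[loc]]$gyro)), 1e-9)
  }
})

test_that("load_recording converts declared units and axis order", {
  set.seed(2)
  n <- 256
  accel <- matrix(rnorm(3 * n), ncol = 3, dimnames = list(NULL, c("ap", "ml", "v")))
  gyro <- matrix(rnorm(3 * n), ncol = 3, dimnames = list(NULL, c("ap", "ml", "v")))
  dir <- withr::local_tempdir()
  # write a manifest by hand: accel in g, gyro in rad/s, axes stored v,ap,ml
  df <- data.frame(t = (1:n - 1) / 128,
                   ax = accel[, "v"] / 9.80665, ay = accel[, "ap"] / 9.80665,
                   az = accel[, "ml"] / 9.80665,
                   gx = gyro[, "v"] * pi / 180, gy = gyro[, "ap"] * pi / 180,
                   gz = gyro[, "ml"] * pi / 180)
  write.csv(format(df, digits = 17), file.path(dir, "lumbar.csv"),
            row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(subject_id = "u1", sampling_rate = 128,
                        sensors = list(lumbar = list(file = "lumbar.csv",
                                                     accel_units = "g",
                                                     gyro_units = "rad/s",
                                                     axis_order = c("v", "ap", "ml")))),
                   file.path(dir, "manifest.yaml"))
  rec <- load_recording(file.path(dir, "manifest.yaml"))
  expect_lt(max(abs(rec$sensors$lumbar$accel - accel)), 1e-9)
  expect_lt(max(abs(rec$sensors$lumbar$gyro - gyro)), 1e-9)
})

test_that("malformed inputs fail with structured errors", {
  set.seed(3)
  mk <- function(n) sensor_stream(matrix(rnorm(3 * n), ncol = 3),
                                  matrix(rnorm(3 * n), ncol = 3))
  # unsynchronized sensors
  expect_error(imu_recording(list(left_foot = mk(100), right_foot = mk(99))),
               "not synchronized")
  # NaN in a stream
  a <- matrix(rnorm(30), ncol = 3); a[5, 2] <- NaN
  expect_error(sensor_stream(a, matrix(rnorm(30), ncol = 3)), "NA/NaN")
  # unknown location
  expect_error(imu_recording(list(wrist = mk(10))), "unknown sensor location")
  # missing channel on disk
  dir <- withr::local_tempdir()
  write.csv(data.frame(t = 0, ax = 1, ay = 1, az = 1, gx = 1, gy = 1),
            file.path(dir, "left_foot.csv"), row.names = FALSE)
  yaml::write_yaml(list(sampling_rate = 128,
                        sensors = list(left_foot = list(file = "left_foot.csv"))),
                   file.path(dir, "manifest.yaml"))
  expect_error(load_recording(file.path(dir, "manifest.yaml")), "gz")
  # FoG-only recording without lumbar loads fine but bout detection errors
  rec <- imu_recording(list(left_foot = mk(1280), right_foot = mk(1280)))
  expect_error(detect_walking(rec), "lumbar")
})

test_that("recordings at other rates are resampled to 128 Hz on load", {
  set.seed(4)
  n <- 64 * 10  # 10 s at 64 Hz
  t <- (1:n - 1) / 64
  sig <- sin(2 * pi * 1 * t)
  df <- data.frame(t = t, ax = sig, ay = sig, az = sig, gx = sig, gy = sig, gz = sig)
  dir <- withr::local_tempdir()
  write.csv(format(df, digits = 17), file.path(dir, "lumbar.csv"),
            row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(sampling_rate = 64,
                        sensors = list(lumbar = list(file = "lumbar.csv"))),
                   file.path(dir, "manifest.yaml"))
  rec <- load_recording(file.path(dir, "manifest.yaml"))
  expect_equal(rec$sampling_rate, 128)
  expect_equal(n_samples(rec), 1280)
  expect_equal(rec$metadata$original_sampling_rate, 64)
  # interior of the resampled sinusoid matches the analytic 128 Hz signal
  t128 <- (1:1280 - 1) / 128
  mid <- 200:1000
  expect_lt(max(abs(rec$sensors$lumbar$accel[mid, "ap"] - sin(2 * pi * t128[mid]))), 0.01)
})
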