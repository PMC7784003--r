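test_that("a fixed seed yields byte-identical recordings", {
  sc <- sim_scenario(30, walking_segments = list(c(5, 25)),
                     fog_schedule = list(c(10, 14)), seed = 101)
  a <- generate_recording(sc)
  b <- generate_recording(sc)
  expect_identical(a$recording$sensors, b$recording$sensors)
  expect_identical(a$truth, b$truth)
})

test_that("invalid schedules are rejected", {
  expect_error(sim_scenario(60, walking_segments = list(c(10, 30)),
                            fog_schedule = list(c(40, 45))), "outside")
  expect_error(sim_scenario(60, walking_segments = list(c(10, 30), c(20, 40))), "overlap")
  expect_error(sim_scenario(60, walking_segments = list(c(10, 70))), "exceed")
  expect_error(sim_scenario(60, walking_segments = list(c(30, 10))), "end > start")
})

test_that("ground-truth labels mirror the schedules at 1-s resolution", {
  sc <- sim_scenario(20, walking_segments = list(c(5, 15)),
                     fog_schedule = list(c(8, 11)), seed = 102)
  truth <- generate_recording(sc)$truth
  lab <- as.character(truth$labels$label)
  expect_equal(lab[1:5], rep("rest", 5))
  expect_equal(lab[6:8], rep("walk", 3))    # seconds 5-7
  expect_equal(lab[9:11], rep("fog", 3))    # seconds 8-10
  expect_equal(lab[12:15], rep("walk", 4))  # seconds 11-14
  expect_equal(lab[16:20], rep("rest", 5))
})

test_that("bilateral correlation structure matches the detector's assumptions", {
  sc <- sim_scenario(100, walking_segments = list(c(5, 95)),
                     fog_schedule = list(c(40, 70)), seed = 103)
  rec <- generate_recording(sc)$recording
  bout <- list(start_index = 5L * 128L, end_index = 95L * 128L)
  fl <- flag_fog_windows(rec, bout)
  fog_win <- fl$start_s >= 40 & fl$end_s <= 70
  walk_win <- fl$end_s <= 40 | fl$start_s >= 70
  expect_gte(mean(fl$corr_lr[walk_win]), 0.8)
  expect_lte(mean(fl$corr_lr[fog_win]), 0.3)
})

test_that("the spectral contract holds: freeze ratios separate fog from gait", {
  sc <- sim_scenario(100, walking_segments = list(c(5, 95)),
                     fog_schedule = list(c(40, 70)), seed = 104)
  rec <- generate_recording(sc)$recording
  bout <- list(start_index = 5L * 128L, end_index = 95L * 128L)
  fl <- flag_fog_windows(rec, bout)
  fog_win <- fl$start_s >= 40 & fl$end_s <= 70
  walk_win <- fl$end_s <= 40 | fl$start_s >= 70
  # at default tremor/locomotor amplitudes nearly every fog window exceeds 10
  expect_gte(mean(fl$freeze_ratio[fog_win] > 10), 0.95)
  expect_true(all(fl$freeze_ratio[walk_win] < 10))
})

test_that("tremor bilateral correlation is tunable", {
  mk <- function(corr, seed) {
    sc <- sim_scenario(70, walking_segments = list(c(5, 65)),
                       fog_schedule = list(c(10, 60)),
                       tremor_bilateral_corr = corr, seed = seed)
    rec <- generate_recording(sc)$recording
    fl <- flag_fog_windows(rec, list(start_index = 5L * 128L, end_index = 65L * 128L))
    mean(fl$corr_lr[fl$start_s >= 10 & fl$end_s <= 60])
  }
  expect_lt(mk(0, 105), 0.2)
  expect_gt(mk(1, 105), mk(0, 105) + 0.3)  # shared tremor restores correlation
})

test_that("cohorts are deterministic and group structure is respected", {
  w <- list(n_days = 1, day_duration_s = 200, walking_segments = list(c(20, 180)))
  a <- generate_cohort(2, 1, w, seed = 9)
  b <- generate_cohort(2, 1, w, seed = 9)
  expect_identical(lapply(a, `[[`, "days"), lapply(b, `[[`, "days"))
  expect_equal(sapply(a, `[[`, "group"), c("freezer", "freezer", "non_freezer"))
  expect_true(all(sapply(a[1:2], `[[`, "fog_fraction") > 0))
  expect_equal(a[[3]]$fog_fraction, 0)
  # non-freezer days carry no fog in the truth
  expect_equal(nrow(a[[3]]$days[[1]]$truth$fog_episodes), 0)
  # all-non-freezer cohort classifies negative at any positive threshold
  c0 <- generate_cohort(0, 3, w, seed = 10)
  weekly <- lapply(c0, analyze_subject)
  expect_true(all(!sapply(weekly, function(x) classify_freezer(x, 0.01)$is_freezer)))
})

test_that("scheduled fog time hits its target and keeps safety margins", {
  set.seed(11)
  segs <- list(c(30, 230), c(330, 530))
  for (target in c(20, 40, 80)) {
    fog <- schedule_fog(segs, target)
    total <- sum(sapply(fog, function(x) x[2] - x[1]))
    expect_equal(total, target)
    m <- do.call(rbind, fog)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(m) > 1) expect_true(all(m[-1, 1] - m[-nrow(m), 2] >= 3))
    # each episode inside a walking segment with margin
    for (i in seq_len(nrow(m))) {
      expect_true(any(m[i, 1] >= sapply(segs, `[`, 1) + 2 &
                      m[i, 2] <= sapply(segs, `[`, 2) - 2))
    }
  }
})
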