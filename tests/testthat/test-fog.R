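test_that("bilateral correlation behaves as a product-moment correlation", {
  t <- (0:127) / 128
  s <- sin(2 * pi * t)
  expect_equal(bilateral_correlation(s, s), 1.0)
  expect_equal(bilateral_correlation(s, -s), -1.0)
  expect_error(bilateral_correlation(s, s[1:64]), "lengths differ")
  # motionless foot: undefined, returned as NA (treated as potential freeze)
  expect_true(is.na(bilateral_correlation(rep(1, 128), s)))
  # brute-force formula agreement on random pairs
  set.seed(42)
  for (i in 1:50) {
    x <- rnorm(128); y <- rnorm(128)
    expect_equal(bilateral_correlation(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("independent noise windows almost never correlate above threshold", {
  set.seed(99)
  r <- replicate(2000, bilateral_correlation(rnorm(128), rnorm(128)))
  # null r is approx N(0, 1/sqrt(127)); |r| >= 0.5 is a > 5 sigma event
  expect_gte(mean(abs(r) < 0.5), 0.999)
})

test_that("freezing ratio matches analytic band energies on constructed tones", {
  fs <- 128
  t <- (0:127) / fs
  # pure locomotor-band tone: all energy in the low band
  expect_equal(freezing_ratio(sin(2 * pi * 1 * t), fs), 0)
  # pure freeze-band tone: epsilon-guarded ratio far above threshold
  expect_gt(freezing_ratio(sin(2 * pi * 5 * t), fs), 10)
  # two tones with amplitude ratio 4 -> energy ratio 16
  x <- 1 * sin(2 * pi * 1 * t) + 4 * sin(2 * pi * 5 * t)
  expect_equal(freezing_ratio(x, fs), 16, tolerance = 1e-6)
  # all-zero window is defined as 0, not NaN
  expect_equal(freezing_ratio(rep(0, 128), fs), 0)
  # DC offset (gravity) must not enter either band
  expect_equal(freezing_ratio(x + 9.81, fs), 16, tolerance = 1e-6)
})

test_that("freezing ratio agrees with a brute-force DFT oracle", {
  set.seed(7)
  fs <- 128
  for (i in 1:10) {
    x <- rnorm(128)
    expected <- dft_band_energy(x, fs, 3, 10) / dft_band_energy(x, fs, 0, 3)
    expect_equal(freezing_ratio(x, fs), expected, tolerance = 1e-6)
  }
})

test_that("window flags fire exactly on trembling seconds inside a bout", {
  sc <- sim_scenario(20, walking_segments = list(c(0, 20)),
                     fog_schedule = list(c(4, 8)), seed = 31)
  rec <- generate_recording(sc)$recording
  bout <- list(start_index = 0L, end_index = 12L * 128L)
  fl <- flag_fog_windows(rec, bout)
  expect_equal(nrow(fl), 12)
  expect_equal(which(fl$is_fog) - 1L, 4:7)
  expect_true(all(fl$is_fog == (fl$potential_by_corr & fl$potential_by_ratio)))

  # clean gait: no flags anywhere
  sc0 <- sim_scenario(20, walking_segments = list(c(0, 20)), seed = 32)
  fl0 <- flag_fog_windows(generate_recording(sc0)$recording, bout)
  expect_false(any(fl0$is_fog))

  # a bout shorter than one window yields no flags
  tiny <- list(start_index = 0L, end_index = 102L)  # 0.8 s
  expect_equal(nrow(flag_fog_windows(rec, tiny)), 0)

  # missing placement sensors named in the error
  expect_error(flag_fog_windows(rec, bout, fog_params(placement = "shins")), "shin")
})

test_that("shin placement runs the identical pipeline on shin sensors", {
  sc <- sim_scenario(30, walking_segments = list(c(0, 30)),
                     fog_schedule = list(c(10, 16)), seed = 33,
                     sensors = c("left_foot", "right_foot", "left_shin",
                                 "right_shin", "lumbar"))
  rec <- generate_recording(sc)$recording
  bout <- list(start_index = 0L, end_index = 30L * 128L)
  fl <- flag_fog_windows(rec, bout, fog_params(placement = "shins"))
  expect_equal(which(fl$is_fog) - 1L, 10:15)
})

test_that("episode assembly merges hesitations of at most the gap limit", {
  # seconds {3,4} and {7}: 2-s hesitation -> one merged episode [3, 8)
  ep <- assemble_episodes(make_flags(c(3, 4, 7), 12), merge_gap_s = 2)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start_s, 3); expect_equal(ep$end_s, 8)
  expect_equal(ep$duration_s, 5)
  expect_equal(as.character(ep$category), "short")
  expect_equal(ep$n_merged_segments, 2)
  # seconds {3,4} and {8}: 3-s hesitation -> two episodes
  ep2 <- assemble_episodes(make_flags(c(3, 4, 8), 12), merge_gap_s = 2)
  expect_equal(ep2$duration_s, c(2, 1))
  expect_equal(as.character(ep2$category), c("short", "very_short"))
  # no flags -> no episodes
  expect_equal(nrow(assemble_episodes(make_flags(integer(0), 12))), 0)
})

test_that("episode categories follow the clinical duration bins", {
  expect_equal(as.character(categorize_episode(c(1, 3, 5, 6, 30))),
               c("very_short", "short", "short", "long", "long"))
  expect_error(categorize_episode(0.5), "resolution")
})

test_that("flagged windows are nested under threshold relaxation", {
  sc <- sim_scenario(60, walking_segments = list(c(0, 60)),
                     fog_schedule = list(c(20, 30)), seed = 41)
  rec <- generate_recording(sc)$recording
  bout <- list(start_index = 0L, end_index = 60L * 128L)
  base <- flag_fog_windows(rec, bout, fog_params())
  # raising the correlation threshold can only add flags
  loose_corr <- flag_fog_windows(rec, bout, fog_params(corr_threshold = 0.8))
  expect_true(all(base$is_fog <= loose_corr$is_fog))
  # lowering the ratio threshold can only add flags
  loose_ratio <- flag_fog_windows(rec, bout, fog_params(ratio_threshold = 5))
  expect_true(all(base$is_fog <= loose_ratio$is_fog))
})

test_that("merging is order-preserving, disjoint, and monotone in the gap", {
  set.seed(55)
  for (i in 1:50) {
    flagged <- which(runif(20) < 0.4) - 1L
    counts <- sapply(0:4, function(g) nrow(assemble_episodes(make_flags(flagged, 20), g)))
    # episode count never increases as the merge gap grows
    expect_true(all(diff(counts) <= 0))
    ep <- assemble_episodes(make_flags(flagged, 20), 2)
    if (nrow(ep) > 1) {
      # disjoint, ordered, gaps strictly above the merge limit
      expect_true(all(ep$start_s[-1] - ep$end_s[-nrow(ep)] > 2))
    }
    # gap 0 reproduces the maximal runs exactly
    ep0 <- assemble_episodes(make_flags(flagged, 20), 0)
    oracle0 <- merge_oracle(flagged, 0)
    expect_equal(ep0$start_s, as.numeric(oracle0$start))
    expect_equal(ep0$end_s, as.numeric(oracle0$end))
  }
})

test_that("the end-to-end detector recovers scheduled episodes and stays silent on clean gait", {
  # no freezing scheduled -> no episodes
  out0 <- generate_recording(sim_scenario(140, walking_segments = list(c(10, 130)), seed = 61))
  det0 <- detect_fog(out0$recording)
  expect_equal(nrow(det0$episodes), 0)
  # short + long episode, boundaries within 1 s
  out <- generate_recording(sim_scenario(140, walking_segments = list(c(10, 130)),
                                         fog_schedule = list(c(30, 34), c(60, 70)),
                                         seed = 61))
  det <- detect_fog(out$recording)
  expect_equal(nrow(det$episodes), 2)
  expect_equal(as.character(det$episodes$category), c("short", "long"))
  expect_lt(max(abs(det$episodes$start_s - c(30, 60))), 1)
  expect_lt(max(abs(det$episodes$end_s - c(34, 70))), 1)
})
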