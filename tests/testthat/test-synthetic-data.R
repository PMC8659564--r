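# Synthetic squat dataset generator: configuration contracts, waveform
# geometry, EMG signal model and reproducibility.

test_that("configuration invariants are enforced", {
  expect_error(synth_config(channel_lags_ms = c(VM = 10, RF = 75, BF = 90,
                                                TA = 50, MG = 80)),
               "20, 200")
  expect_error(synth_config(rom_load_scale = c(1, 0.9, 0.9, 0.7)),
               "strictly decreasing")
  expect_error(synth_config(rom_load_scale = c(1, 0.8)),
               "one entry per load")
  expect_error(synth_config(emg_rate = 0), "positive")
  expect_error(synth_config(cycles_per_load = 0), ">= 1")
  # zero lags are the explicit null-control escape hatch
  expect_silent(synth_config(channel_lags_ms = c(VM = 0, RF = 0, BF = 0,
                                                 TA = 0, MG = 0)))
})

test_that("jitter-free trajectories have the configured cycle geometry", {
  cfg <- synth_config(period_jitter = 0, amp_jitter = 0)
  set.seed(1)
  ang <- generate_angle_trajectory("knee", "none", 5, cfg)
  n_per <- round(cfg$period_s * cfg$kin_rate)
  expect_length(ang, 5 * n_per + 1)
  # five minima-delimited cycles of equal amplitude
  cyc <- segment_cycles(ang, cfg$kin_rate)
  expect_equal(nrow(cyc), 5)
  amps <- vapply(seq_len(5), function(i) {
    seg <- ang[cyc[i, "start"]:cyc[i, "end"]]
    diff(range(seg))
  }, numeric(1))
  expect_equal(amps, rep(cfg$rom_base_deg[["knee"]], 5))
  # amplitude under the heaviest load is rom_load_scale[4] x the no-load one
  ang_h <- generate_angle_trajectory("knee", "100", 5, cfg)
  expect_equal(diff(range(ang_h)) / diff(range(ang)),
               cfg$rom_load_scale[4], tolerance = 1e-12)
  expect_error(generate_angle_trajectory("hip", "none", 5, cfg),
               "unknown joint")
  expect_error(generate_angle_trajectory("knee", "120", 5, cfg),
               "unknown load")
})

test_that("trajectory generation is deterministic given the RNG state", {
  cfg <- synth_config()
  set.seed(5)
  a1 <- generate_angle_trajectory("ankle", "80", 4, cfg)
  set.seed(5)
  a2 <- generate_angle_trajectory("ankle", "80", 4, cfg)
  expect_identical(a1, a2)
})

test_that("EMG channel model: noise floor, band limits, input checks", {
  cfg <- synth_config(noise_sd = 0.05)
  n <- 30000
  set.seed(2)
  quiet <- generate_emg_channel(numeric(n), 0, cfg)
  expect_equal(sd(quiet), cfg$noise_sd, tolerance = 0.05)
  expect_error(generate_emg_channel(c(-1, numeric(99)), 0, cfg),
               "non-negative")
  expect_error(generate_emg_channel(numeric(100), -5, cfg), "lag_ms")

  # spectral mass below 10 Hz and above 450 Hz stays <= 5% of the total
  set.seed(3)
  env <- 1 + 0.5 * sin(2 * pi * (0:(n - 1)) / cfg$emg_rate / 3)
  x <- generate_emg_channel(env, 120, cfg)
  spec <- Mod(stats::fft(x - mean(x)))^2
  freq <- (seq_along(spec) - 1) / n * cfg$emg_rate
  half <- freq <= cfg$emg_rate / 2
  out_band <- half & (freq < 10 | freq > 450)
  expect_lt(sum(spec[out_band]) / sum(spec[half]), 0.05)
})

test_that("a zero-lag channel's envelope peaks in phase with its drive", {
  cfg <- synth_config(noise_sd = 0.02)
  set.seed(4)
  n <- 45000  # 10 cycles at the EMG rate
  env <- 1 - cos(2 * pi * (0:(n - 1)) / 4500)
  x <- generate_emg_channel(env, 0, cfg)
  sm <- dwt_approximation(abs(x), "sym8", 8)
  # brute-force correlation over all lags within +-1 cycle
  lags <- seq(-600, 600, by = 25)
  cc <- vapply(lags, function(k) cross_correlation(sm, env, k), numeric(1))
  expect_lt(abs(lags[which.max(cc)]), 200)  # < ~4% of the cycle length
})

test_that("dataset bookkeeping, ground-truth lags and determinism", {
  ds <- tiny_dataset(n_subjects = 2, cycles_per_load = 2, seed = 9)
  expect_s3_class(ds, "emg_dataset")
  expect_length(ds, 2 * 4)
  r <- ds[[1]]
  expect_identical(dim(r$emg), c(5L, ncol(r$emg)))
  expect_identical(rownames(r$emg), c("VM", "RF", "BF", "TA", "MG"))
  expect_identical(rownames(r$angles), c("knee", "ankle"))
  expect_true(all(is.finite(r$emg)), all(is.finite(r$angles)))
  # same wall-clock span on both time bases (within one kinematic sample)
  expect_lt(abs(ncol(r$emg) / r$emg_rate - ncol(r$angles) / r$kin_rate),
            1 / r$kin_rate)
  expect_true(all(r$truth_lags_ms >= 20 & r$truth_lags_ms <= 200))
  # same subject, different load -> same lags; different subject -> different
  expect_identical(ds[[1]]$truth_lags_ms, ds[[2]]$truth_lags_ms)
  expect_false(identical(ds[[1]]$truth_lags_ms, ds[[5]]$truth_lags_ms))

  ds2 <- tiny_dataset(n_subjects = 2, cycles_per_load = 2, seed = 9)
  expect_identical(ds, ds2)
  ds3 <- tiny_dataset(n_subjects = 2, cycles_per_load = 2, seed = 10)
  expect_false(identical(ds[[1]]$emg, ds3[[1]]$emg))
})

test_that("generation leaves the caller's RNG stream untouched", {
  set.seed(77)
  before <- .Random.seed
  invisible(tiny_dataset(seed = 3))
  expect_identical(before, .Random.seed)
})

test_that("range of motion decreases strictly with load (no jitter)", {
  ds <- tiny_dataset(n_subjects = 2, cycles_per_load = 3, seed = 11,
                     period_jitter = 0, amp_jitter = 0, angle_noise_deg = 0)
  cfg <- attr(ds, "config")
  for (s in c("S01", "S02")) {
    recs <- Filter(function(r) r$subject_id == s, ds)
    roms <- vapply(recs, function(r) diff(range(r$angles["knee", ])),
                   numeric(1))
    expect_identical(vapply(recs, `[[`, character(1), "load"), cfg$loads)
    expect_true(all(diff(roms) < 0))
  }
})
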