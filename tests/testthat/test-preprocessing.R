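# Filtering, segmentation, spline resampling and min-max scaling.

test_that("band-pass rejects DC and out-of-band tones, passes the band", {
  rate <- 1500
  tt <- (0:5999) / rate
  # DC lies in the stop band
  dc <- bandpass_emg(rep(2, 6000), rate)
  interior <- 1000:5000
  expect_lt(max(abs(dc[interior])), 1e-6 * 2)
  # 100 Hz tone passes within 5% (zero-phase doubling of the design order)
  y100 <- bandpass_emg(sin(2 * pi * 100 * tt), rate)
  expect_equal(interior_amplitude(y100, 100, rate), 1, tolerance = 0.05)
  # 5 Hz motion artifact is attenuated below 0.05
  y5 <- bandpass_emg(sin(2 * pi * 5 * tt), rate)
  expect_lt(interior_amplitude(y5, 5, rate), 0.05)
  expect_error(bandpass_emg(rnorm(100), 800), "Nyquist")
})

test_that("kinematic low-pass passes slow motion and kills tremor bands", {
  rate <- 100
  tt <- (0:1999) / rate
  cst <- lowpass_kinematics(rep(3.5, 2000), rate)
  expect_equal(cst[500:1500], rep(3.5, 1001), tolerance = 1e-6)
  y1 <- lowpass_kinematics(sin(2 * pi * 1 * tt), rate)
  expect_equal(interior_amplitude(y1, 1, rate), 1, tolerance = 0.02)
  y30 <- lowpass_kinematics(sin(2 * pi * 30 * tt), rate)
  expect_lt(interior_amplitude(y30, 30, rate), 0.01)
  expect_error(lowpass_kinematics(rnorm(100), 12), "Nyquist")
})

test_that("measured filter gains match the designed magnitude response", {
  # the time-domain measurement must agree with |H(e^iw)|^2 evaluated from
  # the designed coefficients (squared: forward-backward application)
  rate <- 1500
  tt <- (0:5999) / rate
  bf <- signal::butter(4, c(20, 400) / (rate / 2), type = "pass")
  for (f in c(30, 100, 250)) {
    y <- bandpass_emg(sin(2 * pi * f * tt), rate)
    w <- 2 * pi * f / rate
    H <- sum(bf$b * exp(-1i * w * (seq_along(bf$b) - 1))) /
      sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
    expect_equal(interior_amplitude(y, f, rate), Mod(H)^2, tolerance = 0.01)
  }
})

test_that("zero-phase filtering introduces no group delay", {
  # a band-limited signal and its filtered version must peak at lag 0 --
  # downstream lag estimates have to reflect physiology, not filter delay
  rate <- 1500
  set.seed(8)
  tt <- (0:14999) / rate
  x <- sin(2 * pi * 60 * tt) + 0.7 * sin(2 * pi * 150 * tt + 1) +
    0.3 * sin(2 * pi * 320 * tt + 2)
  y <- bandpass_emg(x, rate)
  cc <- vapply(-20:20, function(k) cross_correlation(x, y, k), numeric(1))
  expect_identical((-20:20)[which.max(cc)], 0L)

  x2 <- sin(2 * pi * 2 * (0:1999) / 100)
  y2 <- lowpass_kinematics(x2, 100)
  cc2 <- vapply(-20:20, function(k) cross_correlation(x2, y2, k), numeric(1))
  expect_identical((-20:20)[which.max(cc2)], 0L)
})

test_that("segmentation finds cosine cycles, including endpoint minima", {
  tt <- seq(0, 5, by = 0.01)           # minima at t = 0, 1, ..., 5
  ang <- 10 - 5 * cos(2 * pi * tt)
  cyc <- segment_cycles(ang, rate = 100)
  expect_equal(nrow(cyc), 5)
  expect_equal(attr(cyc, "minima"), seq(1, 501, by = 100))
  # intervals are consecutive and half-open
  expect_identical(cyc[-1, "start"], cyc[-nrow(cyc), "end"])
})

test_that("segmentation rejects signals without qualifying minima", {
  expect_error(segment_cycles(seq(0, 1, length.out = 200), rate = 100),
               "segmentation error")
  expect_error(segment_cycles(rep(1, 100), rate = 100), "segmentation error")
  expect_error(segment_cycles(c(1, 2), rate = 100), "too short")
})

test_that("prominence and separation filter spurious ripples", {
  tt <- seq(0, 4, by = 0.01)
  ang <- 10 - 5 * cos(2 * pi * tt) + 0.1 * sin(2 * pi * 9 * tt)
  cyc <- segment_cycles(ang, rate = 100, min_prominence = 0.1,
                        min_separation_s = 0.5)
  expect_equal(nrow(cyc), 4)  # the 9 Hz ripple creates no extra cycles
})

test_that("spline resampling is exact on low-degree polynomials", {
  # linear segment
  lin <- resample_cycle(seq(0, 1, length.out = 50), 1000)
  expect_equal(lin, seq(0, 1, length.out = 1000), tolerance = 1e-12)
  # endpoint preservation and identity on an already-1000-point segment
  seg <- sin(seq(0, 3, length.out = 1000))
  expect_equal(resample_cycle(seg, 1000), seg, tolerance = 1e-12)
  # quadratic sampled at 50 points, resampled to 1000
  x50 <- seq(0, 1, length.out = 50)
  q <- resample_cycle(x50^2, 1000)
  expect_equal(q, seq(0, 1, length.out = 1000)^2, tolerance = 1e-10)
  expect_error(resample_cycle(c(1, 2, 3), 1000), "too short")
})

test_that("preprocessing a recording yields aligned 1000-point cycles", {
  ds <- tiny_dataset(n_subjects = 1, cycles_per_load = 3, seed = 15)
  cs <- preprocess_recording(ds[[1]])
  expect_s3_class(cs, "cycle_set")
  expect_equal(cs$n_cycles, 3)
  expect_identical(dim(cs$features_raw), c(5L, 3000L))
  expect_identical(dim(cs$targets), c(2L, 3000L))
  expect_identical(ncol(cs$features_raw), ncol(cs$targets))
  expect_identical(cs$cycle_starts, c(1L, 1001L, 2001L))
})

test_that("segmentation + resampling conserves the cycle count", {
  ds <- tiny_dataset(n_subjects = 2, cycles_per_load = 3, seed = 16)
  sets <- lapply(ds, preprocess_recording)
  total <- sum(vapply(sets, function(s) s$n_cycles, integer(1)))
  expect_identical(total, 2L * 4L * 3L)
  dm <- assemble_design_matrix(sets, field = "features_raw")
  expect_identical(ncol(dm$features), total * 1000L)
})

test_that("min-max scaler records training extrema per channel", {
  m <- rbind(c(2, 4, 6), c(0, 5, 10))
  s <- fit_scaler(m)
  expect_equal(s$x_min, c(2, 0))
  expect_equal(s$x_max, c(6, 10))
  expect_equal(normalize(matrix(c(4, 5), 2, 1), s), matrix(0.5, 2, 1))
  n <- normalize(m, s)
  expect_equal(apply(n, 1, min), c(0, 0))
  expect_equal(apply(n, 1, max), c(1, 1))
  expect_error(fit_scaler(rbind(c(1, 1, 1), c(0, 1, 2))), "degenerate")
})

test_that("normalization round-trips exactly and does not clip", {
  set.seed(20)
  for (i in 1:20) {
    m <- matrix(rnorm(5 * 40, sd = 10), 5, 40)
    s <- fit_scaler(m)
    expect_equal(denormalize(normalize(m, s), s), m, tolerance = 1e-12)
    # held-out data outside the training extrema passes through unclipped
    test <- m * 2 + 1
    n <- normalize(test, s)
    expect_true(any(n < 0) || any(n > 1))
    expect_equal(denormalize(n, s), test, tolerance = 1e-12)
  }
  s <- fit_scaler(rbind(c(2, 6)))
  expect_equal(normalize(rbind(c(2, 6)), s), rbind(c(0, 1)))
  expect_equal(denormalize(rbind(c(0, 1)), s), rbind(c(2, 6)))
})
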