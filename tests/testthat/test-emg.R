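test_that("envelope chain: amplification, rectification, unit-DC low-pass", {
  fs <- 200
  expect_equal(preprocess_channel(rep(0, 400), fs), rep(0, 400))

  # 20 dB is x10 in amplitude and the filter has unit DC gain, so a constant
  # 0.5 mV input settles at 5 mV
  env <- preprocess_channel(rep(0.5, 10 * fs), fs)
  expect_equal(tail(env, 1), 5, tolerance = 1e-6)
  expect_lt(abs(envelope_filter_dc_gain() - 1), 1e-9)

  # full-wave rectified sine has mean 2/pi of its amplitude; sample the
  # 50 Hz tone asynchronously (fs = 1000) so the discrete mean converges
  fs2 <- 1000; a <- 0.4
  t <- (seq_len(10 * fs2) - 1) / fs2
  env2 <- preprocess_channel(a * sin(2 * pi * 50 * t), fs2)
  steady <- env2[(2 * fs2):(10 * fs2)]
  expect_equal(mean(steady), 2 / pi * 10 * a, tolerance = 0.02)

  expect_true(all(env2 >= 0))
  expect_error(preprocess_channel(numeric(0), fs), "empty")
  expect_error(preprocess_channel(rep(1, 10), fs = 4, fc = 3), "Nyquist")
})

test_that("rest-subtracted normalization sums to one", {
  expect_equal(normalize_vector(rep(3, 8), rep(1, 8)), rep(0.125, 8))
  expect_error(normalize_vector(rep(1, 8), rep(1, 8)), "zero total activation")
  expect_equal(normalize_vector(c(1, 1, 2, 0, 0, 0, 0, 0) + 5, rep(5, 8)),
               c(0.25, 0.25, 0.5, 0, 0, 0, 0, 0))
  set.seed(101)
  for (i in 1:25) {
    emg <- runif(8, 0, 50); rest <- runif(8, 0, 2)
    out <- normalize_vector(emg, rest)
    expect_lt(abs(sum(out) - 1), 1e-12)
  }
})

test_that("muscle contraction level interpolates rest to max", {
  cal <- test_cal()
  expect_equal(muscle_contraction_level(cal$rest, cal), 0)
  expect_equal(muscle_contraction_level(cal$max, cal), 1)
  expect_equal(muscle_contraction_level((cal$rest + cal$max) / 2, cal), 0.5)
  # clamped against supra-calibration contractions
  expect_equal(muscle_contraction_level(cal$max * 10, cal), 1.5)
  expect_error(calibration_profile(rep(2, 8), rep(2, 8)), "exceed")

  # invariant under per-channel affine rescaling of (emg, rest, max)
  set.seed(7)
  for (i in 1:10) {
    rest <- runif(8, 0, 3); max_ <- rest + runif(8, 1, 50)
    emg <- rest + runif(8) * (max_ - rest)
    a <- runif(8, 0.5, 3); b <- runif(8, 0, 5)
    m1 <- muscle_contraction_level(emg, calibration_profile(rest, max_))
    m2 <- muscle_contraction_level(a * emg + b,
                                   calibration_profile(a * rest + b, a * max_ + b))
    expect_equal(m1, m2, tolerance = 1e-10)
  }
})

test_that("window features match their defining formulas", {
  f <- window_features(rep(3, 5))
  expect_equal(f$mav, 3); expect_equal(f$rms, 3); expect_equal(f$iemg, 15)
  f2 <- window_features(c(1, -1, 1, -1))
  expect_equal(f2$mav, 1); expect_equal(f2$rms, 1); expect_equal(f2$iemg, 4)
  expect_error(window_features(numeric(0)), "empty")

  set.seed(55)
  for (i in 1:10) {
    w <- rnorm(200)
    f <- window_features(w)
    # naive loop oracle
    s_abs <- 0; s_sq <- 0
    for (x in w) { s_abs <- s_abs + abs(x); s_sq <- s_sq + x^2 }
    expect_lt(abs(f$mav - s_abs / length(w)), 1e-12)
    expect_lt(abs(f$iemg - s_abs), 1e-12)
    expect_lt(abs(f$rms - sqrt(s_sq / length(w))), 1e-12)
  }
})

test_that("training samples come from the 2-6 s active window only", {
  cal <- test_cal()
  rec <- gen_training_recording("hold", cal, seed = 31L)
  s <- build_training_samples(rec, "hold", cal)
  expect_length(s$y, 20)
  expect_true(all(s$indices >= 2 * 200 + 1 & s$indices <= 6 * 200))
  expect_equal(dim(s$x), c(20, 8))
  expect_true(all(abs(rowSums(s$x) - 1) < 1e-9))

  short <- emg_recording(matrix(rnorm(5 * 200 * 8), ncol = 8), fs = 200)
  expect_error(build_training_samples(short, "hold", cal), "active window incomplete")

  # even spacing arithmetic: n = 4 over 0-based [400, 1200)
  idx <- build_training_samples(rec, "hold", cal, n_samples = 4)$indices
  expect_equal(idx, c(400, 600, 800, 1000) + 1L)
})

test_that("EMG CSV io round-trips and validates the sampling rate", {
  rec <- emg_recording(matrix(rnorm(160), ncol = 8), fs = 200)
  p <- withr::local_tempfile(fileext = ".csv")
  write_emg_csv(rec, p)
  back <- read_emg_csv(p, fs = 200)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_error(read_emg_csv(p, fs = 500), "differs")
})
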