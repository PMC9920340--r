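test_that("event detection recovers periodic maxima", {
  fs <- 40
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  ev <- detect_events(sin(2 * pi * 0.25 * t), fs, min_separation = 2)
  expect_length(ev$event_times, 15)
  expect_equal(ev$intervals, rep(4, 14), tolerance = 1e-9)

  expect_length(detect_events(rep(1, 100), fs, 1)$event_times, 0)
  expect_true(attr(detect_events(rep(1, 100), fs, 1), "empty"))

  # summed sinusoids: separation contract holds by construction
  x <- sin(2 * pi * 0.3 * t) + 0.3 * sin(2 * pi * 1.1 * t)
  ev2 <- detect_events(x, fs, min_separation = 1.5)
  expect_true(all(ev2$intervals >= 1.5))
})

test_that("cardiorespiratory rates invert interval durations", {
  expect_equal(hr_from_ibi(1.0), 60)
  expect_equal(hr_from_ibi(0.5), 120)
  expect_equal(hr_from_ibi(c(0.75, 0.80)), c(80, 75))
  expect_equal(rr_from_ibi(4.0), 15)
  expect_equal(rr_from_ibi(60), 1)
  expect_equal(rr_from_ibi(c(3, 5)), c(20, 12))
  expect_error(hr_from_ibi(c(0.8, -0.1)), "non-positive")
  # kind checking through ibi_series
  breaths <- ibi_series(c(0, 4, 8), "breath")
  expect_error(hr_from_ibi(breaths), "heart")
  expect_equal(rr_from_ibi(breaths), c(15, 15))
  # constant-rate point process at r bpm recovers r exactly
  beats <- ibi_series(seq(0, 30, by = 60 / 72), "heart")
  expect_equal(hr_from_ibi(beats), rep(72, length(beats$intervals)),
               tolerance = 1e-9)
})

test_that("RMSSD matches hand-computed values and is zero iff constant", {
  expect_equal(rmssd(rep(0.8, 10)), 0)
  expect_equal(rmssd(rep(c(0.8, 1.0), 10)), 0.2)
  expect_equal(rmssd(c(1.0, 1.1, 0.9)), sqrt((0.01 + 0.04) / 2))
  expect_warning(v <- rmssd(0.8), "fewer than 2")
  expect_true(is.na(v))
  set.seed(2)
  for (i in 1:20) {
    iv <- runif(10, 0.6, 1.1)
    expect_gte(rmssd(iv), 0)
    if (length(unique(iv)) > 1) expect_gt(rmssd(iv), 0)
  }
})

test_that("conductance decomposition splits tonic and phasic bands", {
  fs <- 40
  t <- seq(0, 500 - 1 / fs, by = 1 / fs)
  # constant input: all tonic
  comp <- decompose_gsr(rep(3, length(t)), fs)
  mid <- 2000:18000
  expect_equal(comp$scl[mid], rep(3, length(mid)), tolerance = 1e-6)
  expect_equal(comp$scr[mid], rep(0, length(mid)), tolerance = 1e-6)

  # 0.01 Hz ramp-like component lands in SCL, 1 Hz ripple in SCR
  slow <- 0.5 * sin(2 * pi * 0.01 * t)
  fast <- 0.2 * sin(2 * pi * 1 * t)
  comp <- decompose_gsr(3 + slow + fast, fs)
  expect_lt(max(abs(comp$scl[mid] - (3 + slow[mid]))), 0.01)
  expect_lt(max(abs(comp$scr[mid] - fast[mid])), 0.01)

  # complementary: SCL + SCR reconstructs the denoised signal
  expect_lt(max(abs((comp$scl + comp$scr - comp$denoised)[mid])), 1e-4)
  expect_error(decompose_gsr(rep(1, 10), fs), "warm-up")
})

test_that("SCR peak detection thresholds on trough-to-peak rise", {
  fs <- 40
  t <- seq(0, 30, by = 1 / fs)
  kern <- exp(-t / 4) - exp(-t / 1)
  kern <- kern / max(kern)
  x <- numeric(1500)
  x[200:(200 + length(kern) - 1)] <- 0.5 * kern
  pk <- detect_scr_peaks(x[1:1400], min_amplitude = 0.03)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$amplitude, 0.5, tolerance = 0.01)

  expect_equal(nrow(detect_scr_peaks(numeric(100))), 0)
  expect_equal(nrow(detect_scr_peaks(0.01 * x[1:1400] / 0.5, 0.03)), 0)
})

test_that("decomposition + peak detection recover injected event counts", {
  # clean synthetic conductance: events at <= 6/min, amplitudes >= 2x threshold
  fs <- 40
  set.seed(10)
  n <- 300 * fs
  t <- (0:(n - 1)) / fs
  kern <- exp(-t[t <= 30] / 4) - exp(-t[t <= 30] / 1)
  kern <- kern / max(kern)
  ev_t <- sort(runif(25, 10, 250))
  ev_t <- ev_t[c(TRUE, diff(ev_t) > 8)]  # well-separated
  x <- 4 + 0.02 * sin(2 * pi * 0.005 * t)
  for (e in ev_t) {
    i0 <- floor(e * fs) + 1
    idx <- i0:(i0 + length(kern) - 1)
    x[idx] <- x[idx] + runif(1, 0.2, 0.5) * kern
  }
  x <- x[1:n] + rnorm(n, 0, 0.005)
  comp <- decompose_gsr(x, fs)
  pk <- detect_scr_peaks(comp$scr, 0.1)
  expect_lte(abs(nrow(pk) - length(ev_t)), 1)
})

test_that("spectral energy obeys Parseval against the time-domain oracle", {
  fs <- 40
  expect_equal(gsr_energy(numeric(100), fs), 0)
  expect_equal(gsr_energy(c(1, rep(0, 39)), fs), 0.025)
  set.seed(3)
  for (i in 1:100) {
    x <- rnorm(sample(50:400, 1))
    expect_equal(gsr_energy(x, fs), sum(x^2) / fs, tolerance = 1e-9)
  }
})

test_that("acceleration vector magnitude is a rotation-invariant norm", {
  expect_equal(avm(3, 4, 0), 5)
  expect_equal(avm(0, 0, 0), 0)
  expect_error(avm(1:3, 1:2, 1:3), "equal length")
  set.seed(4)
  v <- matrix(rnorm(300), ncol = 3)
  r <- random_rotation()
  vr <- v %*% t(r)
  expect_equal(avm(v[, 1], v[, 2], v[, 3]),
               avm(vr[, 1], vr[, 2], vr[, 3]), tolerance = 1e-12)
})

test_that("baseline normalization is exact and invertible", {
  expect_equal(as.numeric(normalize_baseline(5, 5)), 0)
  expect_equal(as.numeric(normalize_baseline(10, 5)), 1)
  expect_equal(as.numeric(normalize_baseline(90, 75)), 0.2)
  expect_error(normalize_baseline(1:5, 0), "zero-mean")
  set.seed(5)
  x <- runif(100, 50, 120)
  xn <- normalize_baseline(x, 75, "HR")
  expect_equal(75 * (1 + as.numeric(xn)), x, tolerance = 1e-12)
  expect_equal(attr(xn, "channel"), "HR")
})
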