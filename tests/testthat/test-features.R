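test_that("window bookkeeping matches the protocol arithmetic", {
  spec <- window_spec()
  expect_equal(spec$length, 100L)
  expect_equal(window_count(20000, spec), 200L)
  expect_equal(window_count(320000, spec), 3200L)
  expect_warning(n <- window_count(99, spec), "shorter")
  expect_equal(n, 0L)
  # overlap shortens the stride
  expect_equal(window_count(300, window_spec(overlap = 50)), 5L)
  expect_error(window_spec(duration_s = 2.51, sample_rate = 10), "integer")
})

test_that("window statistics match hand arithmetic", {
  s <- window_stats(rep(4.2, 10), fs = 40)
  expect_equal(unname(s), c(4.2, 0, 4.2, 4.2, 0, 0))

  # linear ramp of slope m per second: fd = m, sd = 0
  fs <- 40; m <- 2.5
  ramp <- m * (0:99) / fs
  s <- window_stats(ramp, fs)
  expect_equal(unname(s["fd"]), m)
  expect_equal(unname(s["sd"]), 0)

  s <- window_stats(c(1, 2, 4), fs = 1)
  expect_equal(unname(s[c("mean", "min", "max", "fd", "sd")]),
               c(7 / 3, 1, 4, 1.5, 1))
  expect_equal(unname(s["std"]), sd(c(1, 2, 4)))
  expect_error(window_stats(c(1, 2), 40), "3 samples")
})

test_that("phasic-SCR window features count and measure injected events", {
  fs <- 40
  expect_equal(unname(scr_window_features(numeric(100), fs)), c(0, 0, 0, 0))
  t <- seq(0, 30, by = 1 / fs)
  kern <- exp(-t / 4) - exp(-t / 1); kern <- kern / max(kern)
  x <- numeric(400)
  x[50:(50 + length(kern) - 1)] <- 0.5 * kern
  f <- scr_window_features(x[1:400], fs)
  expect_equal(unname(f["n_pks"]), 1)
  expect_equal(unname(f["A_pks_mean"]), 0.5, tolerance = 0.01)
  expect_equal(unname(f["A_pks_std"]), 0)
  expect_equal(unname(f["E_gsr"]), sum(x[1:400]^2) / fs, tolerance = 1e-9)
})

test_that("PHY and ACC tables have the documented shape and sensor map", {
  proc <- process_study(tiny_study(seed = 17))
  phy <- build_phy_table(proc)
  acc <- build_acc_table(proc)

  expect_equal(length(feature_names(phy)), 40)
  expect_equal(length(feature_names(acc)), 24)
  # statistical block alone is 36 columns
  expect_equal(sum(!grepl("pks|E_gsr", feature_names(phy))), 36)

  sm <- table(sensor_map(phy))
  expect_equal(as.integer(sm[c("CR", "GSR", "ST")]), c(18L, 16L, 6L))
  expect_true(all(sensor_map(acc) == "ACC"))

  # shared windowing: identical rows, labels, boundaries
  expect_equal(nrow(phy), nrow(acc))
  expect_equal(phy$label, acc$label)
  expect_equal(phy$window_start_s, acc$window_start_s)
  expect_equal(phy$subject_id, acc$subject_id)

  # labels exclude BASELINE; no missing values
  expect_true(all(phy$label %in% c("RISK", "NON-RISK")))
  expect_false(anyNA(phy))
  # 2000 task samples per recording -> 20 windows each, 4 recordings
  expect_equal(nrow(phy), 4 * 20)

  # the full 48-column movement variant stays available
  expect_equal(length(feature_names(build_acc_table(proc, variant = "full48"))),
               48)
})

test_that("missing channels are rejected by name", {
  proc <- process_study(tiny_study(seed = 17))
  broken <- proc[[1]]
  broken$channels$HRV <- NULL
  expect_error(build_phy_table(list(broken)), "HRV")
  broken2 <- proc[[1]]
  broken2$channels$acc_head_x <- NULL
  expect_error(build_acc_table(list(broken2)), "acc_head_x")
})

test_that("zero acceleration gives zero AVM features", {
  proc <- process_study(tiny_study(seed = 17))
  p <- proc[[1]]
  for (cn in grep("^acc_|^avm_", names(p$channels), value = TRUE)) {
    p$channels[[cn]] <- 0
  }
  acc <- build_acc_table(list(p))
  avm_cols <- grep("avm", feature_names(acc), value = TRUE)
  expect_true(all(feature_matrix(acc, avm_cols) == 0))
})

test_that("feature tables round-trip through CSV with their sensor map", {
  proc <- process_study(tiny_study(seed = 17))
  phy <- build_phy_table(proc)
  path <- file.path(withr::local_tempdir(), "phy.csv")
  write_feature_table(phy, path)
  back <- read_feature_table(path)
  expect_equal(sensor_map(back), sensor_map(phy))
  expect_equal(feature_matrix(back), feature_matrix(phy), tolerance = 1e-6)
  expect_equal(back$label, phy$label)
})

test_that("mixed-label and baseline windows are dropped", {
  # handcrafted processed recording with a label flip inside a window
  fs <- 40
  n <- 500
  ch <- data.frame(t_s = (0:(n - 1)) / fs,
                   label = c(rep("BASELINE", 100), rep("RISK", 150),
                             rep("NON-RISK", 250)),
                   segment_id = 1L,
                   HR = rnorm(n), HRV = rnorm(n), RR = rnorm(n),
                   SCL = rnorm(n), SCR = rnorm(n), ST = rnorm(n))
  p <- structure(list(subject_id = "S01", env_id = "E1", fs = fs,
                      channels = ch, baseline_means = NULL,
                      scr_min_amplitude = 0.03),
                 class = "processed_recording")
  phy <- build_phy_table(list(p))
  # windows: 1 baseline (dropped), 1 risk, 1 mixed (dropped), 2 non-risk
  expect_equal(nrow(phy), 3)
  expect_equal(sort(unique(phy$label)), c("NON-RISK", "RISK"))
})
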