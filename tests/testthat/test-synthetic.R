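test_that("cohort is sex-balanced with the stated age distribution", {
  set.seed(1)
  cohort <- generate_cohort(8)
  expect_equal(sum(cohort$sex == "male"), 4)
  expect_equal(sum(cohort$sex == "female"), 4)
  expect_true(all(cohort$age >= 18 & cohort$age <= 35))
  expect_true(all(cohort$baseline_hr > 30 & cohort$baseline_hr < 120))
  expect_true(all(cohort$baseline_scl > 0))

  # determinism
  set.seed(99); c1 <- generate_cohort(8)
  set.seed(99); c2 <- generate_cohort(8)
  expect_identical(c1, c2)

  # Monte-Carlo: mean age close to 24 within 3 SE over many cohorts
  set.seed(7)
  ages <- replicate(300, generate_cohort(8)$age)
  se <- 2.6 / sqrt(length(ages))
  expect_lt(abs(mean(ages) - 24), 3 * se)
})

test_that("recordings honour the task sample budget and label bookkeeping", {
  prof <- data.frame(subject_id = "S01", age = 24, sex = "male",
                     baseline_hr = 70, baseline_rr = 14,
                     baseline_scl = 4, baseline_st = 33.5)
  sched <- build_schedule(critical_hr(24, "male"))
  rec <- generate_recording(prof, "E1", sched, seed = 3)
  expect_equal(rec$n_task_samples, 20000)
  expect_equal(sum(rec$data$label != "BASELINE"), 20000)
  # RISK samples = 3 platform segments x 60 s x 40 Hz
  expect_equal(sum(rec$data$label == "RISK"), 3 * 60 * 40)
  expect_equal(sum(rec$data$label == "BASELINE"), 300 * 40)
  expect_true(all(rec$data$gsr_uS > 0))
  expect_true(all(rec$data$label %in% c("BASELINE", "RISK", "NON-RISK")))
  # all channel series share the length
  expect_equal(unique(lengths(rec$data)), nrow(rec$data))
  # segment boundaries are window-aligned (100-sample multiples)
  expect_true(all(rec$segments$n_samples %% 100 == 0))
})

test_that("risk effects raise heart rate over non-risk with exertion off", {
  prof <- data.frame(subject_id = "S01", age = 24, sex = "male",
                     baseline_hr = 70, baseline_rr = 14,
                     baseline_scl = 4, baseline_st = 33.5)
  sched <- build_schedule(196)
  eff <- effect_config(exertion_gain = 0, risk_hr_shift = 12)
  rec <- generate_recording(prof, "E1", sched, eff, seed = 4)
  hr_risk <- mean(rec$data$hr_bpm[rec$data$label == "RISK"])
  hr_non <- mean(rec$data$hr_bpm[rec$data$label == "NON-RISK"])
  expect_gt(hr_risk, hr_non + 1)
  rr_risk <- mean(rec$data$rr_bpm[rec$data$label == "RISK"])
  rr_non <- mean(rec$data$rr_bpm[rec$data$label == "NON-RISK"])
  expect_gt(rr_risk, rr_non + 1)
})

test_that("null effects leave class-conditional channel means indistinguishable", {
  prof <- data.frame(subject_id = "S01", age = 24, sex = "male",
                     baseline_hr = 70, baseline_rr = 14,
                     baseline_scl = 4, baseline_st = 33.5)
  sched <- build_schedule(196, platform_duration_s = 30, baseline_s = 60)
  rec <- generate_recording(prof, "E1", sched, null_effects(),
                            n_task_samples = 7200, seed = 8)
  d <- rec$data
  for (ch in c("hr_bpm", "rr_bpm", "gsr_uS", "st_C")) {
    mr <- mean(d[[ch]][d$label == "RISK"])
    mn <- mean(d[[ch]][d$label == "NON-RISK"])
    tol <- c(hr_bpm = 2, rr_bpm = 1.5, gsr_uS = 0.2, st_C = 0.1)[[ch]]
    expect_lt(abs(mr - mn), tol)
  }
})

test_that("heat-stress environment elevates skin temperature and SCL drift", {
  prof <- data.frame(subject_id = "S01", age = 24, sex = "male",
                     baseline_hr = 70, baseline_rr = 14,
                     baseline_scl = 4, baseline_st = 33.5)
  sched <- build_schedule(196)
  e1 <- generate_recording(prof, "E1", sched, seed = 21)
  e2 <- generate_recording(prof, "E2", sched, seed = 22)
  expect_gt(mean(e2$data$st_C), mean(e1$data$st_C) + 1)
  slope <- function(r) unname(coef(lm(r$data$gsr_uS ~ r$data$t_s))[2])
  expect_gt(slope(e2), slope(e1))
})

test_that("study scaling and on-disk round trip are deterministic", {
  study <- tiny_study(seed = 13)
  expect_length(study$recordings, 4)  # 2 subjects x 2 environments
  expect_equal(sum(study$manifest$n_task_samples), 4 * 2000)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(tiny_study(seed = 13), d1)
  write_study(tiny_study(seed = 13), d2)
  for (f in list.files(d1, pattern = "csv$")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }

  rec <- read_recording(file.path(d1, "S01_E2.csv"))
  expect_s3_class(rec, "raw_recording")
  expect_equal(rec$subject_id, "S01")
  expect_equal(rec$env_id, "E2")
  orig <- study$recordings[[which(study$manifest$file == "S01_E2.csv")]]
  expect_equal(rec$data$gsr_uS, orig$data$gsr_uS, tolerance = 1e-6)
  expect_equal(rec$n_task_samples, orig$n_task_samples)
})
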