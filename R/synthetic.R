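# Synthetic study generator: labeled multichannel recordings with the
# statistical structure the downstream analysis assumes (cardiorespiratory
# exertion/risk responses, electrodermal tonic drift + phasic events, heat
# effects, and accelerometry constructed to be class-uninformative).

#' Generate a synthetic subject cohort
#'
#' Draws subject profiles matching the study population: ages from a rounded
#' Normal(24, 2.6) clipped to 18--35, sexes exactly balanced (for even `n`),
#' and rest-condition baselines in plausible adult ranges (HR 55--80 bpm,
#' RR 12--18 breaths/min, SCL 2--8 microsiemens, ST 32.5--34.5 degrees C).
#'
#' @param n_subjects Cohort size, default 8.
#' @return A data.frame with one row per subject: `subject_id`, `age`, `sex`,
#'   `baseline_hr`, `baseline_rr`, `baseline_scl`, `baseline_st`.
#' @export
generate_cohort <- function(n_subjects = 8) {
  stopifnot(n_subjects >= 1)
  age <- pmin(35, pmax(18, round(stats::rnorm(n_subjects, 24, 2.6))))
  sex <- sample(rep(c("male", "female"), length.out = n_subjects))
  data.frame(
    subject_id   = sprintf("S%02d", seq_len(n_subjects)),
    age          = as.integer(age),
    sex          = sex,
    baseline_hr  = round(stats::runif(n_subjects, 55, 80), 1),
    baseline_rr  = round(stats::runif(n_subjects, 12, 18), 1),
    baseline_scl = round(stats::runif(n_subjects, 2, 8), 2),
    baseline_st  = round(stats::runif(n_subjects, 32.5, 34.5), 2),
    stringsAsFactors = FALSE
  )
}

#' Effect configuration for the synthetic generator
#'
#' Collects every tunable effect size of the generator. The defaults encode
#' the qualitative physiology the analysis assumes: balance-perturbation
#' (RISK) segments elicit a sympathetic response (heart-rate shift, inflated
#' inter-beat jitter, respiration shift, a burst of skin-conductance
#' responses), treadmill exertion drives heart rate toward the segment's HRc
#' threshold, the hot environment (E2) elevates skin temperature and drifts
#' the skin-conductance level upward, and accelerometry is drawn from a
#' class-shared amplitude distribution so the two classes are
#' near-indistinguishable from motion alone.
#'
#' @param risk_hr_shift RISK heart-rate elevation over the recovering
#'   baseline trajectory, bpm.
#' @param ibi_jitter_sd Baseline beat-to-beat interval jitter SD, seconds.
#' @param risk_ibi_jitter_mult Multiplier on interval jitter during RISK.
#' @param risk_rr_shift RISK respiration-rate elevation, breaths/min.
#' @param scr_rate_risk,scr_rate_nonrisk,scr_rate_baseline Skin-conductance
#'   response event rates, events/min, per segment label.
#' @param scr_amplitude_range Uniform range of SCR event amplitudes,
#'   microsiemens.
#' @param heat_st_shift Skin-temperature elevation in E2, degrees C.
#' @param heat_scl_offset Immediate SCL elevation in E2, microsiemens.
#' @param scl_drift_e1,scl_drift_e2 SCL upward drift, microsiemens/min.
#' @param st_exertion_drift Skin-temperature rise over the task portion of a
#'   session, degrees C.
#' @param exertion_gain Scales how far segment HR/RR targets depart from the
#'   subject baseline (1 = full protocol response, 0 = no response; used by
#'   [null_effects()]).
#' @param rr_exertion_coef Respiration-rate rise per bpm of heart-rate rise.
#' @param hr_tau_up,hr_tau_down First-order heart-rate response time
#'   constants (rising / recovering), seconds.
#' @param acc_class_overlap Fraction of platform segments whose oscillation
#'   amplitude is drawn from the class-shared distribution (near 1 keeps
#'   accelerometry non-discriminative).
#' @param gsr_noise_sd,st_noise_sd,resp_noise_sd,acc_noise_sd Additive
#'   measurement-noise SDs per channel.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(risk_hr_shift = 12,
                          ibi_jitter_sd = 0.025,
                          risk_ibi_jitter_mult = 1.8,
                          risk_rr_shift = 6,
                          scr_rate_risk = 10,
                          scr_rate_nonrisk = 2,
                          scr_rate_baseline = 1,
                          scr_amplitude_range = c(0.1, 0.6),
                          heat_st_shift = 1.5,
                          heat_scl_offset = 0.5,
                          scl_drift_e1 = 0.02,
                          scl_drift_e2 = 0.10,
                          st_exertion_drift = 0.3,
                          exertion_gain = 1,
                          rr_exertion_coef = 0.15,
                          hr_tau_up = 35,
                          hr_tau_down = 45,
                          acc_class_overlap = 0.97,
                          gsr_noise_sd = 0.01,
                          st_noise_sd = 0.02,
                          resp_noise_sd = 0.05,
                          acc_noise_sd = 0.15) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("scr_rate_risk", "scr_rate_nonrisk",
                             "scr_rate_baseline")]) >= 0),
            acc_class_overlap >= 0, acc_class_overlap <= 1,
            length(scr_amplitude_range) == 2,
            all(scr_amplitude_range > 0))
  class(cfg) <- "effect_config"
  cfg
}

#' Null-world effect configuration
#'
#' Zero class-informative structure: no RISK shifts, equal SCR rates, no
#' exertion response, no heat or time drifts (segment order is deterministic,
#' so any time-varying process would leak the label), and fully class-shared
#' accelerometry. Used to calibrate the pipeline at chance level.
#'
#' @param ... Overrides passed on to [effect_config()].
#' @return An `effect_config`.
#' @export
null_effects <- function(...) {
  effect_config(risk_hr_shift = 0, risk_ibi_jitter_mult = 1,
                risk_rr_shift = 0, scr_rate_risk = 2, scr_rate_nonrisk = 2,
                scr_rate_baseline = 2, heat_st_shift = 0,
                heat_scl_offset = 0, scl_drift_e1 = 0, scl_drift_e2 = 0,
                st_exertion_drift = 0, exertion_gain = 0,
                acc_class_overlap = 1, ...)
}

# Closed-form first-order segment response: value after t seconds.
.hr_step <- function(hr0, drive, tau, t) drive + (hr0 - drive) * exp(-t / tau)

# Resolve per-segment sample counts for one session. Treadmill segments end
# when the first-order HR trajectory crosses their stop threshold (rounded up
# to a whole window), capped so the labeled task fits n_task_samples exactly;
# leftover budget becomes a NON-RISK walking segment.
.resolve_segments <- function(schedule, profile, effects, fs, n_task_samples,
                              window_samples = 100) {
  segs <- as.data.frame(schedule)
  n_platform <- sum(segs$kind == "platform_risk")
  plat_n <- round(segs$duration_s[segs$kind == "platform_risk"][1] * fs)
  if (plat_n %% window_samples != 0)
    stop("platform duration must be a whole number of feature windows")
  n_tread <- sum(segs$kind == "treadmill")
  task_budget <- n_task_samples - n_platform * plat_n
  if (task_budget < n_tread * window_samples)
    stop("n_task_samples too small for the schedule's platform segments")
  cap <- (task_budget %/% n_tread %/% window_samples) * window_samples

  g <- effects$exertion_gain
  hr0 <- profile$baseline_hr
  out <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$kind == "baseline_rest") {
      drive <- profile$baseline_hr
      n <- round(s$duration_s * fs)
    } else if (s$kind == "platform_risk") {
      drive <- profile$baseline_hr + effects$risk_hr_shift
      n <- plat_n
    } else { # treadmill
      drive <- profile$baseline_hr + g * (s$hr_stop_bpm + 15 - profile$baseline_hr)
      if (drive > s$hr_stop_bpm && hr0 < s$hr_stop_bpm) {
        t_cross <- effects$hr_tau_up *
          log((drive - hr0) / (drive - s$hr_stop_bpm))
        n <- ceiling(t_cross * fs / window_samples) * window_samples
        n <- min(max(n, window_samples), cap)
      } else {
        n <- cap
      }
    }
    tau <- if (drive >= hr0) effects$hr_tau_up else effects$hr_tau_down
    out[[i]] <- data.frame(kind = s$kind, label = s$label, n_samples = n,
                           drive_bpm = drive, tau_s = tau,
                           stringsAsFactors = FALSE)
    hr0 <- .hr_step(hr0, drive, tau, n / fs)
  }
  out <- do.call(rbind, out)
  fill <- n_task_samples - sum(out$n_samples[out$kind != "baseline_rest"])
  if (fill < 0) stop("internal: task budget overrun")
  if (fill > 0) {
    drive <- profile$baseline_hr + g * 25
    out <- rbind(out, data.frame(
      kind = "walk_fill", label = "NON-RISK", n_samples = fill,
      drive_bpm = drive,
      tau_s = if (drive >= hr0) effects$hr_tau_up else effects$hr_tau_down,
      stringsAsFactors = FALSE))
  }
  out$segment_id <- seq_len(nrow(out))
  out$start_sample <- cumsum(c(1, out$n_samples))[seq_len(nrow(out))]
  out
}

# Piecewise-exponential HR target trace over all segments.
.hr_target_trace <- function(segments, profile, fs) {
  hr0 <- profile$baseline_hr
  trace <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    t <- seq_len(s$n_samples) / fs
    trace[[i]] <- .hr_step(hr0, s$drive_bpm, s$tau_s, t)
    hr0 <- trace[[i]][s$n_samples]
  }
  unlist(trace)
}

# Event point process following a per-sample instantaneous rate (per minute),
# with Gaussian interval jitter (per-sample SD trace, seconds).
.point_process <- function(rate_trace, jitter_trace, fs, t_end,
                           min_interval = 0.25) {
  n_max <- ceiling(t_end * max(rate_trace) / 60) + 50
  times <- numeric(n_max)
  t <- stats::runif(1, 0, 60 / rate_trace[1])  # random phase for first event
  k <- 0
  while (t < t_end) {
    k <- k + 1
    times[k] <- t
    i <- min(length(rate_trace), floor(t * fs) + 1)
    ibi <- 60 / rate_trace[i] + stats::rnorm(1, 0, jitter_trace[i])
    t <- t + max(min_interval, ibi)
  }
  times[seq_len(k)]
}

# Sample-and-hold of per-completed-interval values (device-like channel).
.hold_intervals <- function(event_times, values, t_samples) {
  if (length(values) < 1) return(rep(NA_real_, length(t_samples)))
  # interval j completes at event_times[j + 1]
  idx <- findInterval(t_samples, event_times[-1]) # completed intervals so far
  idx <- pmin(pmax(idx, 1), length(values))
  values[idx]
}

# Smooth slow wander: cubic interpolation through independent knots.
.slow_wander <- function(n, fs, sd, knot_spacing_s = 60) {
  if (sd <= 0 || n < 2) return(numeric(n))
  k <- max(4, ceiling(n / fs / knot_spacing_s) + 2)
  kt <- seq(0, (n - 1) / fs, length.out = k)
  stats::spline(kt, stats::rnorm(k, 0, sd), xout = (0:(n - 1)) / fs)$y
}

# Bi-exponential SCR kernel (1 s rise, 4 s decay), unit peak amplitude.
.scr_kernel <- function(fs, rise = 1, decay = 4, dur_s = 30) {
  t <- seq(0, dur_s, by = 1 / fs)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

#' Generate one synthetic subject-environment recording
#'
#' Simulates a full session at `fs` Hz: a rest baseline followed by the
#' labeled task protocol (platform RISK segments interleaved with
#' threshold-terminated treadmill segments, plus a NON-RISK walking filler
#' so the labeled task portion has exactly `n_task_samples` samples).
#' Heartbeats and breaths are generated as point processes following
#' first-order rate dynamics and projected onto the sampling grid by
#' sample-and-hold of the last completed interval, mirroring how wearable
#' devices report instantaneous HR/RR. Skin conductance is a tonic level
#' (baseline + heat offset + drift + slow wander) plus phasic bi-exponential
#' events at label-dependent Poisson rates; skin temperature carries heat and
#' exertion drifts; accelerometers oscillate with class-shared amplitudes.
#'
#' @param profile One-row subject data.frame (see [generate_cohort()]).
#' @param env_id `"E1"` (temperate) or `"E2"` (heat stress).
#' @param schedule A [build_schedule()] result.
#' @param effects An [effect_config()].
#' @param n_task_samples Labeled task samples per session (default 20000,
#'   i.e. 500 s at 40 Hz). The rest baseline is recorded in addition to this
#'   budget.
#' @param fs Sampling rate, Hz.
#' @param seed Optional integer seed for this recording.
#' @return A `raw_recording`: list with `subject_id`, `env_id`, `fs`, `data`
#'   (one row per sample: `t_s, hr_bpm, ibi_s, resp_au, rr_bpm, gsr_uS, st_C,
#'   acc_chest_x/y/z, acc_head_x/y/z, temp_C, rh_pct, label, segment_id`),
#'   `segments` (realised segment table), `profile`, and generator
#'   ground-truth `events` (beat/breath/SCR times) for diagnostics.
#' @export
generate_recording <- function(profile, env_id, schedule,
                               effects = effect_config(),
                               n_task_samples = 20000, fs = 40,
                               seed = NULL) {
  stopifnot(inherits(schedule, "protocol_schedule"),
            is.data.frame(profile), nrow(profile) == 1,
            env_id %in% c("E1", "E2"))
  if (!is.null(seed)) set.seed(seed)
  env <- env_conditions()
  env <- env[env$env_id == env_id, ]
  is_e2 <- env_id == "E2"

  segments <- .resolve_segments(schedule, profile, effects, fs, n_task_samples)
  n <- sum(segments$n_samples)
  t_s <- (0:(n - 1)) / fs
  label <- rep(segments$label, segments$n_samples)
  seg_id <- rep(segments$segment_id, segments$n_samples)
  is_risk <- label == "RISK"
  task_start <- segments$start_sample[segments$kind != "baseline_rest"][1]

  # --- cardiorespiratory -----------------------------------------------
  hr_target <- .hr_target_trace(segments, profile, fs)
  jitter_hr <- effects$ibi_jitter_sd * (profile$baseline_hr / hr_target)
  jitter_hr[is_risk] <- jitter_hr[is_risk] * effects$risk_ibi_jitter_mult
  beats <- .point_process(hr_target, jitter_hr, fs, t_s[n] + 1 / fs)
  ibi_h <- diff(beats)
  hr_bpm <- .hold_intervals(beats, 60 / ibi_h, t_s)
  ibi_s <- .hold_intervals(beats, ibi_h, t_s)

  rr_target <- profile$baseline_rr +
    effects$rr_exertion_coef * pmax(0, hr_target - profile$baseline_hr) +
    effects$risk_rr_shift * is_risk
  jitter_rr <- rep(0.15, n)
  jitter_rr[is_risk] <- jitter_rr[is_risk] * effects$risk_ibi_jitter_mult
  breaths <- .point_process(rr_target, jitter_rr, fs, t_s[n] + 1 / fs,
                            min_interval = 1)
  ibi_r <- diff(breaths)
  rr_bpm <- .hold_intervals(breaths, 60 / ibi_r, t_s)
  # respiration waveform with maxima exactly at breath events
  phase <- findInterval(t_s, breaths)
  j <- pmin(pmax(phase, 1), length(ibi_r))
  frac <- (t_s - breaths[j]) / ibi_r[j]
  resp_au <- cos(2 * pi * (j + frac)) +
    stats::rnorm(n, 0, effects$resp_noise_sd)

  # --- electrodermal ----------------------------------------------------
  drift <- if (is_e2) effects$scl_drift_e2 else effects$scl_drift_e1
  scl <- profile$baseline_scl +
    (if (is_e2) effects$heat_scl_offset else 0) +
    drift * t_s / 60 +
    .slow_wander(n, fs, 0.05)
  rates <- c(BASELINE = effects$scr_rate_baseline,
             `NON-RISK` = effects$scr_rate_nonrisk,
             RISK = effects$scr_rate_risk)
  kernel <- .scr_kernel(fs)
  scr <- numeric(n + length(kernel))
  scr_times <- numeric(0); scr_amps <- numeric(0)
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    rate <- rates[[s$label]]
    n_ev <- stats::rpois(1, rate * s$n_samples / fs / 60)
    if (n_ev == 0) next
    ev_t <- sort(stats::runif(n_ev, 0, s$n_samples / fs)) +
      (s$start_sample - 1) / fs
    amp <- stats::runif(n_ev, effects$scr_amplitude_range[1],
                        effects$scr_amplitude_range[2])
    for (e in seq_len(n_ev)) {
      i0 <- floor(ev_t[e] * fs) + 1
      idx <- i0:(i0 + length(kernel) - 1)
      scr[idx] <- scr[idx] + amp[e] * kernel
    }
    scr_times <- c(scr_times, ev_t); scr_amps <- c(scr_amps, amp)
  }
  gsr_uS <- pmax(0.01, scl + scr[seq_len(n)] +
                   stats::rnorm(n, 0, effects$gsr_noise_sd))

  # --- skin temperature -------------------------------------------------
  task_T <- n_task_samples / fs
  progress <- pmax(0, (t_s - (task_start - 1) / fs)) / task_T
  st_C <- profile$baseline_st +
    (if (is_e2) effects$heat_st_shift else 0) +
    effects$st_exertion_drift * pmin(1, progress) +
    .slow_wander(n, fs, 0.03) +
    stats::rnorm(n, 0, effects$st_noise_sd)

  # --- accelerometry ----------------------------------------------------
  acc <- matrix(0, n, 6,
                dimnames = list(NULL, c("acc_chest_x", "acc_chest_y",
                                        "acc_chest_z", "acc_head_x",
                                        "acc_head_y", "acc_head_z")))
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    idx <- s$start_sample:(s$start_sample + s$n_samples - 1)
    tt <- t_s[idx]
    if (s$kind == "baseline_rest") {
      amp <- 0.05
    } else {
      amp <- stats::rlnorm(1, log(1.5), 0.4)
      if (s$kind == "platform_risk" &&
          stats::runif(1) > effects$acc_class_overlap) {
        amp <- amp * 0.25  # class-specific sway only beyond the overlap
      }
    }
    f <- stats::runif(1, 1.4, 2.2)
    ph <- stats::runif(6, 0, 2 * pi)
    gains <- c(0.6, 0.4, 1.0, 0.45, 0.3, 0.7)
    freqs <- c(f, f, 2 * f, f, f, 2 * f)
    for (ch in 1:6) {
      acc[idx, ch] <- gains[ch] * amp * sin(2 * pi * freqs[ch] * tt + ph[ch])
    }
  }
  acc <- acc + matrix(stats::rnorm(n * 6, 0, effects$acc_noise_sd), n, 6)

  # --- ambient trace ----------------------------------------------------
  temp_C <- env$temp_mean + .slow_wander(n, fs, env$temp_sd, 120)
  rh_pct <- pmin(99, pmax(0, env$rh_mean + .slow_wander(n, fs, env$rh_sd, 120)))

  rec <- list(
    subject_id = profile$subject_id, env_id = env_id, fs = fs,
    n_task_samples = sum(segments$n_samples[segments$kind != "baseline_rest"]),
    data = data.frame(
      t_s = t_s, hr_bpm = hr_bpm, ibi_s = ibi_s, resp_au = resp_au,
      rr_bpm = rr_bpm, gsr_uS = gsr_uS, st_C = st_C,
      acc_chest_x = acc[, 1], acc_chest_y = acc[, 2], acc_chest_z = acc[, 3],
      acc_head_x = acc[, 4], acc_head_y = acc[, 5], acc_head_z = acc[, 6],
      temp_C = temp_C, rh_pct = rh_pct, label = label, segment_id = seg_id,
      stringsAsFactors = FALSE),
    segments = segments, profile = profile,
    events = list(beats = beats, breaths = breaths,
                  scr_times = scr_times, scr_amplitudes = scr_amps)
  )
  class(rec) <- "raw_recording"
  rec
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s %s: %d samples @ %g Hz (%d task), %d segments\n",
              x$subject_id, x$env_id, nrow(x$data), x$fs,
              x$n_task_samples, nrow(x$segments)))
  invisible(x)
}

#' Generate a full synthetic study
#'
#' One recording per subject and environment, fully reproducible from a
#' single study seed (the cohort and one substream seed per recording are
#' drawn from it).
#'
#' @param n_subjects Number of subjects (>= 2), default 8.
#' @param envs Environments to record, default `c("E1", "E2")`.
#' @param effects An [effect_config()].
#' @param seed Study-level integer seed.
#' @param n_task_samples Labeled task samples per recording, default 20000.
#' @param fs Sampling rate, Hz.
#' @param schedule_args Named list of overrides for [build_schedule()]
#'   (e.g. `platform_duration_s` for scaled-down studies).
#' @return A `risk_study`: list with `cohort`, `recordings` (list of
#'   `raw_recording`), `manifest` (data.frame), `effects`, `seed`.
#' @export
generate_study <- function(n_subjects = 8, envs = c("E1", "E2"),
                           effects = effect_config(), seed = 1,
                           n_task_samples = 20000, fs = 40,
                           schedule_args = list()) {
  stopifnot(n_subjects >= 2, all(envs %in% c("E1", "E2")))
  set.seed(seed)
  cohort <- generate_cohort(n_subjects)
  grid <- expand.grid(subject = seq_len(n_subjects), env = envs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec_seeds <- sample.int(.Machine$integer.max - 1, nrow(grid))
  recordings <- vector("list", nrow(grid))
  manifest <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    prof <- cohort[grid$subject[i], ]
    sched <- do.call(build_schedule,
                     c(list(hrc = critical_hr(prof$age, prof$sex)),
                       schedule_args))
    rec <- generate_recording(prof, grid$env[i], sched, effects,
                              n_task_samples = n_task_samples, fs = fs,
                              seed = rec_seeds[i])
    recordings[[i]] <- rec
    manifest[[i]] <- data.frame(
      subject_id = prof$subject_id, env_id = grid$env[i],
      seed = rec_seeds[i],
      file = sprintf("%s_%s.csv", prof$subject_id, grid$env[i]),
      n_samples = nrow(rec$data), n_task_samples = rec$n_task_samples,
      n_risk = sum(rec$data$label == "RISK"),
      n_nonrisk = sum(rec$data$label == "NON-RISK"),
      stringsAsFactors = FALSE)
  }
  study <- list(cohort = cohort, recordings = recordings,
                manifest = do.call(rbind, manifest),
                effects = effects, seed = seed)
  class(study) <- "risk_study"
  study
}

#' @export
print.risk_study <- function(x, ...) {
  cat(sprintf("<risk_study> %d subjects x %d environments, %d recordings, %d task samples total (seed %d)\n",
              nrow(x$cohort), length(unique(x$manifest$env_id)),
              length(x$recordings), sum(x$manifest$n_task_samples), x$seed))
  invisible(x)
}

#' Write a study to disk as CSV recordings plus a JSON manifest
#'
#' @param study A `risk_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "risk_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(study$recordings)) {
    rec <- study$recordings[[i]]
    data.table::fwrite(rec$data, file.path(dir, study$manifest$file[i]))
  }
  manifest <- list(seed = study$seed, cohort = study$cohort,
                   effects = unclass(study$effects),
                   recordings = study$manifest)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read one recording back from its CSV
#'
#' Reconstructs a `raw_recording` from the on-disk schema (generator
#' ground-truth events are not persisted; the segment table is rebuilt from
#' the `segment_id`/`label` columns).
#'
#' @param path CSV path.
#' @param subject_id,env_id Metadata (taken from the file name
#'   `<subject>_<env>.csv` when omitted).
#' @param fs Sampling rate, Hz.
#' @return A `raw_recording`.
#' @export
read_recording <- function(path, subject_id = NULL, env_id = NULL, fs = 40) {
  d <- as.data.frame(data.table::fread(path))
  need <- c("t_s", "hr_bpm", "ibi_s", "resp_au", "rr_bpm", "gsr_uS", "st_C",
            "acc_chest_x", "acc_chest_y", "acc_chest_z",
            "acc_head_x", "acc_head_y", "acc_head_z", "label", "segment_id")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("recording CSV misses columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(subject_id) || is.null(env_id)) {
    parts <- strsplit(sub("\\.csv$", "", basename(path)), "_")[[1]]
    if (is.null(subject_id)) subject_id <- parts[1]
    if (is.null(env_id)) env_id <- parts[length(parts)]
  }
  rle_id <- rle(d$segment_id)
  segments <- data.frame(
    segment_id = rle_id$values,
    label = d$label[cumsum(rle_id$lengths)],
    n_samples = rle_id$lengths,
    start_sample = cumsum(c(1, rle_id$lengths))[seq_along(rle_id$values)],
    stringsAsFactors = FALSE)
  rec <- list(subject_id = subject_id, env_id = env_id, fs = fs,
              n_task_samples = sum(d$label != "BASELINE"),
              data = d, segments = segments, profile = NULL, events = NULL)
  class(rec) <- "raw_recording"
  rec
}
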