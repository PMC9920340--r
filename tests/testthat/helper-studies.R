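# Scaled synthetic studies shared across test files (cached per session so
# acceptance and unit tests do not regenerate identical studies).

.study_cache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (!exists(key, envir = .study_cache)) {
    assign(key, force(expr), envir = .study_cache)
  }
  get(key, envir = .study_cache)
}

# Desk-scale study: full 8-subject x 2-environment design with 30 s platform
# segments and a 150 s task budget (60 windows per recording). The balanced
# variant (used for null calibration) gives platform and treadmill equal
# time so both classes have matched priors.
scaled_tables <- function(seed, kind = c("default", "null"),
                          n_subjects = 8) {
  kind <- match.arg(kind)
  .cached(paste("tables", seed, kind, n_subjects, sep = "_"), {
    effects <- if (kind == "null") null_effects() else effect_config()
    n_task <- if (kind == "null") 7200 else 6000
    study <- generate_study(
      n_subjects = n_subjects, effects = effects, seed = seed,
      n_task_samples = n_task,
      schedule_args = list(platform_duration_s = 30, baseline_s = 60))
    proc <- process_study(study)
    list(phy = build_phy_table(proc), acc = build_acc_table(proc))
  })
}

# Tiny 2-subject study for structural unit tests.
tiny_study <- function(seed = 5, effects = effect_config()) {
  generate_study(n_subjects = 2, effects = effects, seed = seed,
                 n_task_samples = 2000,
                 schedule_args = list(platform_duration_s = 10,
                                      baseline_s = 30))
}

# Median fold accuracy chance band: binomial around 0.5 on the fold's
# window count deflated by a design effect of 3 (windows within a segment
# are correlated, so the effective sample size is smaller than the count).
chance_band <- function(n_fold, deff = 3) {
  half <- 1.96 * sqrt(0.25 / (n_fold / deff))
  c(0.5 - half, 0.5 + half)
}
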