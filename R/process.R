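# Turns a raw recording into the per-sample analysis channels: held HR/RR,
# trailing-window RMSSD, tonic/phasic conductance, vector magnitudes, and
# rest-baseline normalization of the slow physiological channels.

# (time, value) pairs of the held-interval channel: one entry per change.
.held_events <- function(t_s, values) {
  ok <- which(!is.na(values))
  if (!length(ok)) return(list(t = numeric(0), v = numeric(0)))
  idx <- ok[c(TRUE, diff(values[ok]) != 0)]
  list(t = t_s[idx], v = values[idx])
}

# Trailing-window RMSSD over an interval sequence, held at sample times.
.trailing_rmssd <- function(ev_t, ev_v, t_s, window_s) {
  if (length(ev_v) < 3) return(rep(NA_real_, length(t_s)))
  lo <- findInterval(ev_t - window_s, ev_t) + 1  # first event inside window
  per_event <- rep(NA_real_, length(ev_v))
  for (j in seq_along(ev_v)) {
    if (j - lo[j] >= 1) {
      per_event[j] <- sqrt(mean(diff(ev_v[lo[j]:j])^2))
    }
  }
  idx <- pmin(pmax(findInterval(t_s, ev_t), 1), length(ev_v))
  out <- per_event[idx]
  if (anyNA(out)) {
    first <- which(!is.na(out))[1]
    if (is.na(first)) stop("trailing RMSSD undefined everywhere: too few beats")
    out[seq_len(first - 1)] <- out[first]
    # interior NAs (sparse windows) carry the last defined value forward
    for (i in which(is.na(out))) out[i] <- out[i - 1]
  }
  out
}

#' Process a raw recording into analysis channels
#'
#' Computes, at the recording's sampling grid: held instantaneous HR and RR,
#' heart-rate variability as RMSSD over a trailing buffer of beats (a 2.5 s
#' feature window holds too few beats to compute RMSSD from scratch), the
#' tonic (SCL) and phasic (SCR) conductance components, and the two
#' acceleration vector magnitudes. HR, HRV, RR, SCL and ST are then
#' normalized against their means over the rest-baseline segment; the phasic
#' SCR is kept in raw microsiemens (zero-mean, so ratio normalization is
#' ill-posed).
#'
#' @param rec A `raw_recording`.
#' @param hrv_window_s Trailing beat-buffer length for RMSSD, seconds.
#' @param scr_min_amplitude Stored on the result for downstream peak
#'   features, microsiemens.
#' @param tonic_cutoff,noise_cutoff,filter_order Passed to
#'   [decompose_gsr()].
#' @param baseline_means Optional named vector `(HR, HRV, RR, SCL, ST)`
#'   overriding the rest-segment means (required if the recording has no
#'   BASELINE samples).
#' @return A `processed_recording`: list with `subject_id`, `env_id`, `fs`,
#'   `baseline_means`, and `channels` (data.frame: `t_s`, `label`,
#'   `segment_id`, normalized `HR`, `HRV`, `RR`, `SCL`, `ST`, raw `SCR`,
#'   the six acceleration axes and `avm_chest`, `avm_head`).
#' @export
process_recording <- function(rec, hrv_window_s = 30,
                              scr_min_amplitude = 0.03,
                              tonic_cutoff = 0.1, noise_cutoff = 5,
                              filter_order = 4, baseline_means = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  d <- rec$data
  fs <- rec$fs

  beats <- .held_events(d$t_s, d$ibi_s)
  hrv <- .trailing_rmssd(beats$t, beats$v, d$t_s, hrv_window_s)
  comp <- decompose_gsr(d$gsr_uS, fs, noise_cutoff, tonic_cutoff, filter_order)

  raw <- list(HR = d$hr_bpm, HRV = hrv, RR = d$rr_bpm,
              SCL = comp$scl, ST = d$st_C)
  base_mask <- d$label == "BASELINE"
  if (is.null(baseline_means)) {
    if (!any(base_mask))
      stop("recording has no BASELINE samples; supply baseline_means")
    baseline_means <- vapply(raw, function(x) mean(x[base_mask]), numeric(1))
  } else {
    miss <- setdiff(names(raw), names(baseline_means))
    if (length(miss)) stop("baseline_means misses: ", paste(miss, collapse = ", "))
    baseline_means <- baseline_means[names(raw)]
  }

  norm <- mapply(function(x, m, nm) normalize_baseline(x, m, nm),
                 raw, baseline_means, names(raw), SIMPLIFY = FALSE)

  channels <- data.frame(
    t_s = d$t_s, label = d$label, segment_id = d$segment_id,
    HR = as.numeric(norm$HR), HRV = as.numeric(norm$HRV),
    RR = as.numeric(norm$RR), SCL = as.numeric(norm$SCL),
    SCR = comp$scr, ST = as.numeric(norm$ST),
    acc_chest_x = d$acc_chest_x, acc_chest_y = d$acc_chest_y,
    acc_chest_z = d$acc_chest_z,
    acc_head_x = d$acc_head_x, acc_head_y = d$acc_head_y,
    acc_head_z = d$acc_head_z,
    avm_chest = avm(d$acc_chest_x, d$acc_chest_y, d$acc_chest_z),
    avm_head = avm(d$acc_head_x, d$acc_head_y, d$acc_head_z),
    stringsAsFactors = FALSE)

  out <- list(subject_id = rec$subject_id, env_id = rec$env_id, fs = fs,
              channels = channels, baseline_means = baseline_means,
              scr_min_amplitude = scr_min_amplitude)
  class(out) <- "processed_recording"
  out
}

#' Process every recording of a study
#'
#' @param study A `risk_study` from [generate_study()].
#' @param ... Passed to [process_recording()].
#' @return List of `processed_recording`.
#' @export
process_study <- function(study, ...) {
  stopifnot(inherits(study, "risk_study"))
  lapply(study$recordings, process_recording, ...)
}
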