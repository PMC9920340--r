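# Formula-defined signal processing: event detection and inter-event
# intervals, cardiorespiratory metrics, GSR tonic/phasic decomposition and
# peak detection, spectral signal energy, acceleration vector magnitude, and
# rest-baseline normalization.

#' Inter-beat / inter-breath interval series
#'
#' @param event_times Strictly increasing event times in seconds.
#' @param kind `"heart"` or `"breath"`.
#' @return An `ibi_series`: list with `event_times`, `intervals`
#'   (successive differences, seconds) and `kind`. Fewer than two events
#'   yield an empty interval vector flagged with attribute `empty = TRUE`.
#' @export
ibi_series <- function(event_times, kind = c("heart", "breath")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(event_times))
  if (is.unsorted(event_times, strictly = TRUE))
    stop("event_times must be strictly increasing")
  out <- list(event_times = event_times, intervals = diff(event_times),
              kind = kind)
  class(out) <- "ibi_series"
  attr(out, "empty") <- length(event_times) < 2
  out
}

#' Detect periodic events in a waveform
#'
#' Finds local maxima (e.g. maximum rib-cage expansion in a respiration
#' waveform) above a prominence floor, enforcing a minimum separation by
#' greedily keeping the highest peaks.
#'
#' @param waveform Uniformly sampled numeric series.
#' @param fs Sampling rate, Hz.
#' @param min_separation Minimum event separation, seconds.
#' @param prominence_frac Height floor as a fraction of the signal range
#'   above the minimum (default 0.5: events must reach the upper half of the
#'   excursion). A constant signal has no events.
#' @param kind Passed to [ibi_series()].
#' @return An [ibi_series()] of detected events (times at sample resolution).
#' @export
detect_events <- function(waveform, fs, min_separation,
                          prominence_frac = 0.5, kind = "breath") {
  stopifnot(is.numeric(waveform), fs > 0, min_separation > 0)
  n <- length(waveform)
  if (n < 3) return(ibi_series(numeric(0), kind))
  rng <- range(waveform)
  if (diff(rng) == 0) return(ibi_series(numeric(0), kind))
  floor_h <- rng[1] + prominence_frac * diff(rng)
  x <- waveform
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  cand <- cand[x[cand] >= floor_h]
  if (!length(cand)) return(ibi_series(numeric(0), kind))
  # greedy: highest first, suppress neighbours closer than min_separation
  min_gap <- round(min_separation * fs)
  keep <- logical(length(cand))
  for (i in order(-x[cand], cand)) {
    if (!any(keep & abs(cand - cand[i]) < min_gap)) keep[i] <- TRUE
  }
  ibi_series((sort(cand[keep]) - 1) / fs, kind)
}

.intervals_of <- function(x, kind = NULL) {
  if (inherits(x, "ibi_series")) {
    if (!is.null(kind) && x$kind != kind)
      stop("expected ", kind, "-kind intervals, got ", x$kind)
    x$intervals
  } else {
    stopifnot(is.numeric(x))
    x
  }
}

#' Instantaneous heart rate from inter-beat intervals
#'
#' `HR(i) = 60 / IBI(i)`, beats per minute.
#'
#' @param ibi An [ibi_series()] of kind `"heart"`, or a numeric vector of
#'   intervals in seconds.
#' @return Numeric vector, bpm per interval.
#' @export
hr_from_ibi <- function(ibi) {
  iv <- .intervals_of(ibi, "heart")
  if (any(iv <= 0)) stop("non-positive inter-beat interval")
  60 / iv
}

#' Instantaneous respiration rate from inter-breath intervals
#'
#' `RR(i) = 60 / IBI(i)`, breaths per minute.
#'
#' @param ibi An [ibi_series()] of kind `"breath"`, or a numeric vector of
#'   intervals in seconds.
#' @return Numeric vector, breaths/min per interval.
#' @export
rr_from_ibi <- function(ibi) {
  iv <- .intervals_of(ibi, "breath")
  if (any(iv <= 0)) stop("non-positive inter-breath interval")
  60 / iv
}

#' Root mean square of successive differences (RMSSD)
#'
#' Time-domain heart-rate-variability metric over an interval sequence:
#' the square root of the mean of the squared successive interval
#' differences (N - 1 differences for N intervals).
#'
#' @param ibi An [ibi_series()] or numeric vector of intervals in seconds.
#' @return RMSSD in seconds; `NA` (with a warning) for fewer than two
#'   intervals.
#' @export
rmssd <- function(ibi) {
  iv <- .intervals_of(ibi)
  if (length(iv) < 2) {
    warning("RMSSD undefined for fewer than 2 intervals")
    return(NA_real_)
  }
  sqrt(mean(diff(iv)^2))
}

# Zero-phase filtering with odd-reflection edge padding: extends the series
# at both ends by its point-reflection before filtfilt, suppressing the
# boundary transients a zero-padded filter produces on signals with a
# non-zero level (essential for the very low tonic cutoff).
.filtfilt_refl <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  if (pad < 1) return(signal::filtfilt(filt, x))
  head_ext <- 2 * x[1] - x[(pad + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(filt, c(head_ext, x, tail_ext))
  y[(pad + 1):(pad + n)]
}

#' Decompose skin conductance into tonic and phasic components
#'
#' Denoises the raw conductance with a 5 Hz low-pass Butterworth filter,
#' then splits it into the tonic skin-conductance level (SCL, 0.1 Hz
#' low-pass) and the phasic skin-conductance response (SCR, 0.1 Hz
#' high-pass). All filters are applied forward-backward (zero phase), so the
#' low- and high-pass branches are complementary: `SCL + SCR` reconstructs
#' the denoised signal up to edge effects.
#'
#' @param gsr Conductance series, microsiemens.
#' @param fs Sampling rate, Hz (> 10).
#' @param noise_cutoff,tonic_cutoff Filter cutoffs, Hz.
#' @param order Butterworth order (default 4).
#' @return A `gsr_components` list: `scl`, `scr`, `denoised`.
#' @export
decompose_gsr <- function(gsr, fs, noise_cutoff = 5, tonic_cutoff = 0.1,
                          order = 4) {
  stopifnot(is.numeric(gsr), fs > 10)
  n_min <- 3 * (2 * order + 1)
  if (length(gsr) < n_min)
    stop("series shorter than filter warm-up (need >= ", n_min, " samples)")
  ny <- fs / 2
  # pad long enough for the slow tonic filter to settle
  pad <- min(length(gsr) - 1, ceiling(2 / tonic_cutoff * fs))
  den <- .filtfilt_refl(signal::butter(order, noise_cutoff / ny, "low"),
                        gsr, pad)
  scl <- .filtfilt_refl(signal::butter(order, tonic_cutoff / ny, "low"),
                        den, pad)
  scr <- .filtfilt_refl(signal::butter(order, tonic_cutoff / ny, "high"),
                        den, pad)
  out <- list(scl = scl, scr = scr, denoised = den)
  class(out) <- "gsr_components"
  out
}

#' Detect phasic skin-conductance response peaks
#'
#' A peak is a local maximum of the phasic (SCR) trace whose rise from the
#' preceding trough is at least `min_amplitude`; the recorded amplitude is
#' that rise. The default 0.03 microsiemens is the permissive end of the
#' conventional 0.03--0.05 band.
#'
#' @param scr Phasic conductance series, microsiemens.
#' @param min_amplitude Minimum trough-to-peak rise, microsiemens.
#' @return data.frame with `index` and `amplitude` (possibly zero rows).
#' @export
detect_scr_peaks <- function(scr, min_amplitude = 0.03) {
  stopifnot(is.numeric(scr), min_amplitude > 0)
  n <- length(scr)
  empty <- data.frame(index = integer(0), amplitude = numeric(0))
  if (n < 3) return(empty)
  pk <- which(scr[2:(n - 1)] > scr[1:(n - 2)] & scr[2:(n - 1)] >= scr[3:n]) + 1
  if (!length(pk)) return(empty)
  prev <- c(1L, pk[-length(pk)])
  rise <- vapply(seq_along(pk), function(i) {
    scr[pk[i]] - min(scr[prev[i]:pk[i]])
  }, numeric(1))
  keep <- rise >= min_amplitude
  data.frame(index = pk[keep], amplitude = rise[keep])
}

#' Spectral energy of a conductance signal
#'
#' Integrates the auto-spectrum of the discrete Fourier transform over
#' frequency, normalised so that it equals the time-domain energy
#' `sum(x^2) * dt` (Parseval).
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @return Energy in (signal units)^2 * s.
#' @export
gsr_energy <- function(x, fs) {
  stopifnot(is.numeric(x), all(is.finite(x)), fs > 0)
  if (!length(x)) return(0)
  sum(Mod(stats::fft(x))^2) / length(x) / fs
}

#' Acceleration vector magnitude
#'
#' Elementwise Euclidean norm of a tri-axial acceleration series.
#'
#' @param ax,ay,az Equal-length acceleration series, m/s^2.
#' @return Numeric series, m/s^2.
#' @export
avm <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ax) != length(az))
    stop("acceleration axes must have equal length")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Normalize a channel against its rest-baseline mean
#'
#' `x_norm = (x - baseline_mean) / baseline_mean`: the dimensionless
#' deviation of a physiological channel from its subject-specific rest
#' value. Not applicable to (near) zero-mean channels such as the phasic
#' SCR, for which the division is ill-posed.
#'
#' @param x Numeric series.
#' @param baseline_mean Mean of the channel over the rest baseline, same
#'   units as `x`; must be non-zero.
#' @param channel Optional channel name, stored as an attribute.
#' @return Numeric series with attributes `baseline_mean` and `channel`.
#' @export
normalize_baseline <- function(x, baseline_mean, channel = NULL) {
  stopifnot(is.numeric(x), is.numeric(baseline_mean),
            length(baseline_mean) == 1)
  if (!is.finite(baseline_mean) || baseline_mean == 0)
    stop("baseline mean must be non-zero and finite; ",
         "zero-mean channels (e.g. phasic SCR) cannot be baseline-normalized")
  out <- (x - baseline_mean) / baseline_mean
  attr(out, "baseline_mean") <- baseline_mean
  if (!is.null(channel)) attr(out, "channel") <- channel
  out
}
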