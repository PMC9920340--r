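#' Critical heart rate
#'
#' Age- and sex-dependent heart-rate ceiling used to terminate exertion
#' segments of the session protocol: `220 - age` for males and
#' `206 - 0.88 * age` for females.
#'
#' @param age Age in years (numeric, `> 0` for physiological use; the formula
#'   itself is defined for any non-negative age). Vectorised.
#' @param sex `"male"` or `"female"` (recycled against `age`).
#' @return Critical heart rate in beats per minute.
#' @examples
#' critical_hr(24, "male")    # 196
#' critical_hr(25, "female")  # 184
#' @export
critical_hr <- function(age, sex) {
  stopifnot(is.numeric(age), all(is.finite(age)), all(age >= 0))
  sex <- as.character(sex)
  bad <- !sex %in% c("male", "female")
  if (any(bad)) {
    stop("unknown sex token(s): ", paste(unique(sex[bad]), collapse = ", "),
         "; expected \"male\" or \"female\"")
  }
  ifelse(sex == "male", 220 - age, 206 - 0.88 * age)
}

#' Environmental risk coefficient (ERC)
#'
#' Heat-stress index combining ambient temperature and relative humidity:
#' `ERC = T + 0.1 * RH`. Values at or below 29 indicate unrestricted work,
#' values of 34 and above an increasing heat-risk factor (see
#' [erc_category()]).
#'
#' @param temperature Ambient temperature in degrees Celsius.
#' @param humidity Relative humidity in percent, in `[0, 99]`.
#' @return Dimensionless coefficient.
#' @examples
#' erc(22.19, 44.58)  # 26.648
#' @export
erc <- function(temperature, humidity) {
  stopifnot(is.numeric(temperature), is.numeric(humidity))
  if (any(!is.finite(humidity)) || any(humidity < 0 | humidity > 99)) {
    stop("humidity must lie in [0, 99] %RH")
  }
  temperature + 0.1 * humidity
}

#' Heat-stress category of an ERC value
#'
#' Partitions the coefficient into action bands: `low` (<= 29, unrestricted
#' work), `moderate` (drink frequently) and `high` (>= 34, avoid
#' high-intensity work).
#'
#' @param erc Coefficient as returned by [erc()]. Vectorised.
#' @return Character vector in `{"low", "moderate", "high"}`.
#' @export
erc_category <- function(erc) {
  stopifnot(is.numeric(erc), all(is.finite(erc)))
  ifelse(erc <= 29, "low", ifelse(erc >= 34, "high", "moderate"))
}

#' Ambient summaries of the two session environments
#'
#' Mean and standard deviation of temperature and relative humidity recorded
#' in the temperate environment (E1) and the heat-stress environment (E2),
#' used both by the synthetic-study generator and to characterise the heat
#' exposure via [erc()].
#'
#' @return A data.frame with one row per environment: `env_id`, `temp_mean`,
#'   `temp_sd` (degrees C), `rh_mean`, `rh_sd` (%RH).
#' @export
env_conditions <- function() {
  data.frame(
    env_id    = c("E1", "E2"),
    temp_mean = c(22.19, 28.81),
    temp_sd   = c(0.55, 0.53),
    rh_mean   = c(44.58, 52.80),
    rh_sd     = c(1.97, 4.94),
    stringsAsFactors = FALSE
  )
}

#' Session schedule template
#'
#' Builds the ordered segment list of one environment session: a 5-minute
#' rest baseline, then three 1-minute balance-perturbation (stabilometric
#' platform) segments labelled RISK interleaved with two treadmill exertion
#' segments labelled NON-RISK. Treadmill segments have no fixed duration:
#' they terminate when the simulated (or measured) heart rate crosses a
#' fraction of the critical heart rate `hrc`.
#'
#' @param hrc Critical heart rate in bpm (see [critical_hr()]).
#' @param thresholds Two HRc fractions terminating the first and second
#'   treadmill segment. Default `c(0.60, 0.85)`; the second stage can be
#'   raised (e.g. to 0.90) for more demanding protocols.
#' @param platform_duration_s Duration of each platform (RISK) segment in
#'   seconds, default 60.
#' @param baseline_s Duration of the initial rest baseline in seconds,
#'   default 300.
#' @param speeds_kmh,inclines_pct Treadmill speed (km/h) and incline (%) for
#'   the two exertion stages.
#' @return A data.frame of class `protocol_schedule`, one row per segment:
#'   `kind` (`baseline_rest`, `platform_risk`, `treadmill`), `label`
#'   (`BASELINE`, `RISK`, `NON-RISK`), `duration_s` (NA for
#'   threshold-terminated segments), `hr_fraction`, `hr_stop_bpm`,
#'   `speed_kmh`, `incline_pct`.
#' @export
build_schedule <- function(hrc,
                           thresholds = c(0.60, 0.85),
                           platform_duration_s = 60,
                           baseline_s = 300,
                           speeds_kmh = c(5, 6),
                           inclines_pct = c(6, 9)) {
  stopifnot(is.numeric(hrc), length(hrc) == 1, hrc > 0,
            length(thresholds) == 2, all(thresholds > 0 & thresholds < 1),
            platform_duration_s > 0, baseline_s > 0)
  seg <- function(kind, label, duration_s, hr_fraction = NA_real_,
                  speed = NA_real_, incline = NA_real_) {
    data.frame(kind = kind, label = label, duration_s = duration_s,
               hr_fraction = hr_fraction,
               hr_stop_bpm = if (is.na(hr_fraction)) NA_real_ else hr_fraction * hrc,
               speed_kmh = speed, incline_pct = incline,
               stringsAsFactors = FALSE)
  }
  sched <- rbind(
    seg("baseline_rest", "BASELINE", baseline_s),
    seg("platform_risk", "RISK", platform_duration_s),
    seg("treadmill", "NON-RISK", NA_real_, thresholds[1], speeds_kmh[1], inclines_pct[1]),
    seg("platform_risk", "RISK", platform_duration_s),
    seg("treadmill", "NON-RISK", NA_real_, thresholds[2], speeds_kmh[2], inclines_pct[2]),
    seg("platform_risk", "RISK", platform_duration_s)
  )
  attr(sched, "hrc") <- hrc
  class(sched) <- c("protocol_schedule", "data.frame")
  sched
}

#' Serialise a schedule to JSON
#'
#' @param schedule A `protocol_schedule` from [build_schedule()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
schedule_to_json <- function(schedule, path = NULL) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  x <- list(hrc_bpm = attr(schedule, "hrc"),
            segments = as.data.frame(schedule))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
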