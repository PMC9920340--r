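# Windowing and construction of the physiological (PHY) and movement (ACC)
# feature tables: six window statistics per channel plus four phasic-SCR
# extras, with a feature-to-sensor map carried as table metadata.

.META_COLS <- c("subject_id", "env_id", "window_start_s", "label")
.STAT_NAMES <- c("mean", "std", "min", "max", "fd", "sd")

#' Feature-window specification
#'
#' @param duration_s Window length in seconds (default 2.5).
#' @param sample_rate Hz (default 40). `duration_s * sample_rate` must be a
#'   whole number of samples.
#' @param overlap Overlap between consecutive windows, samples (default 0:
#'   non-overlapping windows, the only choice consistent with the
#'   100-samples-per-window bookkeeping of the study protocol).
#' @return A `window_spec` list with `length` and `stride` in samples.
#' @export
window_spec <- function(duration_s = 2.5, sample_rate = 40, overlap = 0) {
  len <- duration_s * sample_rate
  if (abs(len - round(len)) > 1e-9)
    stop("duration_s * sample_rate must be an integer number of samples")
  len <- as.integer(round(len))
  stopifnot(overlap >= 0, overlap < len)
  out <- list(duration_s = duration_s, sample_rate = sample_rate,
              overlap = as.integer(overlap), length = len,
              stride = len - as.integer(overlap))
  class(out) <- "window_spec"
  out
}

#' Number of feature windows in a series
#'
#' @param n_samples Series length in samples.
#' @param spec A [window_spec()].
#' @return `floor((n_samples - length) / stride) + 1`; 0 (with a warning)
#'   for series shorter than one window.
#' @export
window_count <- function(n_samples, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"), n_samples >= 0)
  if (n_samples < spec$length) {
    warning("series shorter than one window")
    return(0L)
  }
  as.integer((n_samples - spec$length) %/% spec$stride + 1)
}

#' The six window statistics
#'
#' Mean, standard deviation (n-1 divisor), minimum, maximum, mean first
#' derivative and mean second derivative of a window. Derivatives are finite
#' differences scaled by the sampling rate (units/s and units/s^2), so
#' feature values do not depend on the sampling rate.
#'
#' @param values Window samples (length >= 3; the second derivative is
#'   undefined below that).
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector `mean, std, min, max, fd, sd`.
#' @export
window_stats <- function(values, fs) {
  stopifnot(is.numeric(values), fs > 0)
  if (length(values) < 3)
    stop("window_stats needs at least 3 samples (second derivative)")
  d1 <- diff(values)
  c(mean = mean(values), std = stats::sd(values),
    min = min(values), max = max(values),
    fd = mean(d1) * fs, sd = mean(diff(d1)) * fs^2)
}

#' Phasic-SCR window features
#'
#' Peak count, mean and standard deviation of peak amplitudes (zero when no
#' peak, zero SD for a single peak), and the spectral energy of the window.
#'
#' @param scr Phasic conductance window, microsiemens.
#' @param fs Sampling rate, Hz.
#' @param min_amplitude Peak threshold for [detect_scr_peaks()].
#' @return Named numeric vector `n_pks, A_pks_mean, A_pks_std, E_gsr`.
#' @export
scr_window_features <- function(scr, fs, min_amplitude = 0.03) {
  pk <- detect_scr_peaks(scr, min_amplitude)
  c(n_pks = nrow(pk),
    A_pks_mean = if (nrow(pk)) mean(pk$amplitude) else 0,
    A_pks_std = if (nrow(pk) > 1) stats::sd(pk$amplitude) else 0,
    E_gsr = gsr_energy(scr, fs))
}

# Windows of one recording that carry a single non-BASELINE label.
.eligible_windows <- function(labels, spec) {
  n <- length(labels)
  starts <- seq.int(1L, n - spec$length + 1L, by = spec$stride)
  keep <- vapply(starts, function(s) {
    w <- labels[s:(s + spec$length - 1L)]
    w[1] != "BASELINE" && all(w == w[1])
  }, logical(1))
  starts[keep]
}

.as_feature_table <- function(df, sensor_map) {
  feat <- setdiff(names(df), .META_COLS)
  stopifnot(setequal(names(sensor_map), feat))
  if (anyNA(df)) stop("feature table contains missing values")
  attr(df, "sensor_map") <- sensor_map[feat]
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Assemble a feature table from a precomputed matrix
#'
#' Constructor used for handcrafted tables (tests, external data): attaches
#' the metadata columns and the feature-to-sensor map.
#'
#' @param features Numeric matrix or data.frame of feature columns.
#' @param label Window labels (`RISK` / `NON-RISK`).
#' @param subject_id,env_id Per-window metadata (recycled).
#' @param sensor_map Named character vector mapping each feature column to a
#'   sensor group (`CR`, `GSR`, `ST`, `ACC`); defaults to `CR` for all.
#' @param window_start_s Optional per-window start times.
#' @return A `feature_table`.
#' @export
feature_table <- function(features, label, subject_id, env_id = "E1",
                          sensor_map = NULL, window_start_s = NULL) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (is.null(sensor_map))
    sensor_map <- stats::setNames(rep("CR", ncol(features)), names(features))
  df <- cbind(data.frame(subject_id = rep_len(subject_id, n),
                         env_id = rep_len(env_id, n),
                         window_start_s = if (is.null(window_start_s))
                           seq_len(n) else window_start_s,
                         label = rep_len(label, n),
                         stringsAsFactors = FALSE),
              features)
  .as_feature_table(df, sensor_map)
}

#' Feature column names of a table
#' @param table A `feature_table`.
#' @return Character vector.
#' @export
feature_names <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  setdiff(names(table), .META_COLS)
}

#' Feature-to-sensor map of a table
#' @param table A `feature_table`.
#' @return Named character vector (feature -> `CR`/`GSR`/`ST`/`ACC`).
#' @export
sensor_map <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  attr(table, "sensor_map")
}

#' Numeric feature matrix of a table
#' @param table A `feature_table`.
#' @param features Optional subset of feature columns.
#' @return Numeric matrix, windows x features.
#' @export
feature_matrix <- function(table, features = NULL) {
  if (is.null(features)) features <- feature_names(table)
  as.matrix(table[, features, drop = FALSE])
}

#' @export
print.feature_table <- function(x, ...) {
  sm <- sensor_map(x)
  cat(sprintf("<feature_table> %d windows x %d features (%s); labels: %s\n",
              nrow(x), length(sm),
              paste(sprintf("%s:%d", names(table(sm)), table(sm)),
                    collapse = ", "),
              paste(sprintf("%s:%d", names(table(x$label)), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}

# Subsetting keeps the class and map.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(.META_COLS %in% names(out))) {
    sm <- attr(x, "sensor_map")
    .as_feature_table(as.data.frame(out), sm[intersect(names(sm), names(out))])
  } else out
}

.rbind_tables <- function(parts) {
  df <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(df) <- NULL
  df
}

#' Build the physiological (PHY) feature table
#'
#' Six window statistics for each of the six normalized physiological
#' channels HR, HRV, RR, SCL, |SCR| and ST (the phasic SCR being zero-mean,
#' its statistics are computed on the absolute value), plus four phasic-SCR
#' extras (peak count, mean and SD of peak amplitudes, spectral energy):
#' 40 feature columns. Windows containing BASELINE samples or a label change
#' are dropped.
#'
#' @param processed A `processed_recording` or list of them.
#' @param spec A [window_spec()].
#' @param scr_min_amplitude SCR peak threshold, microsiemens (defaults to
#'   the value stored on the processed recording).
#' @return A `feature_table` with sensor groups CR (HR/HRV/RR, 18 columns),
#'   GSR (SCL and |SCR| statistics plus the 4 extras, 16) and ST (6).
#' @export
build_phy_table <- function(processed, spec = window_spec(),
                            scr_min_amplitude = NULL) {
  if (inherits(processed, "processed_recording")) processed <- list(processed)
  phy_channels <- c("HR", "HRV", "RR", "SCL", "SCR", "ST")
  parts <- lapply(processed, function(p) {
    stopifnot(inherits(p, "processed_recording"))
    ch <- p$channels
    miss <- setdiff(phy_channels, names(ch))
    if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
    thr <- if (is.null(scr_min_amplitude)) p$scr_min_amplitude else scr_min_amplitude
    starts <- .eligible_windows(ch$label, spec)
    rows <- lapply(starts, function(s) {
      idx <- s:(s + spec$length - 1L)
      stats6 <- unlist(lapply(phy_channels, function(cn) {
        x <- ch[[cn]][idx]
        if (cn == "SCR") x <- abs(x)
        stats::setNames(window_stats(x, p$fs),
                        paste0(cn, "_", .STAT_NAMES))
      }))
      extras <- scr_window_features(ch$SCR[idx], p$fs, thr)
      names(extras) <- paste0("SCR_", names(extras))
      c(stats6, extras)
    })
    feat <- as.data.frame(do.call(rbind, rows))
    cbind(data.frame(subject_id = p$subject_id, env_id = p$env_id,
                     window_start_s = ch$t_s[starts],
                     label = ch$label[starts], stringsAsFactors = FALSE),
          feat)
  })
  df <- .rbind_tables(parts)
  feat <- setdiff(names(df), .META_COLS)
  grp <- ifelse(grepl("^(HR|HRV|RR)_", feat), "CR",
                ifelse(grepl("^ST_", feat), "ST", "GSR"))
  .as_feature_table(df, stats::setNames(grp, feat))
}

#' Build the movement (ACC) feature table
#'
#' Statistics of the two tri-axial accelerometers (chest, head) and their
#' vector magnitudes over the same windows as the PHY table. The default
#' `compact24` variant uses `{mean, std, max}` per channel
#' (2 sensors x 4 channels x 3 statistics = 24 columns); `full48` applies
#' all six statistics.
#'
#' @param processed A `processed_recording` or list of them.
#' @param spec A [window_spec()].
#' @param variant `"compact24"` or `"full48"`.
#' @return A `feature_table` with every column mapped to sensor group `ACC`.
#' @export
build_acc_table <- function(processed, spec = window_spec(),
                            variant = c("compact24", "full48")) {
  variant <- match.arg(variant)
  if (inherits(processed, "processed_recording")) processed <- list(processed)
  stats_use <- if (variant == "compact24") c("mean", "std", "max") else .STAT_NAMES
  acc_channels <- c(chest_x = "acc_chest_x", chest_y = "acc_chest_y",
                    chest_z = "acc_chest_z", chest_avm = "avm_chest",
                    head_x = "acc_head_x", head_y = "acc_head_y",
                    head_z = "acc_head_z", head_avm = "avm_head")
  parts <- lapply(processed, function(p) {
    stopifnot(inherits(p, "processed_recording"))
    ch <- p$channels
    miss <- setdiff(unname(acc_channels), names(ch))
    if (length(miss)) stop("missing sensor channel(s): ",
                           paste(miss, collapse = ", "))
    starts <- .eligible_windows(ch$label, spec)
    rows <- lapply(starts, function(s) {
      idx <- s:(s + spec$length - 1L)
      unlist(lapply(names(acc_channels), function(nm) {
        st <- window_stats(ch[[acc_channels[[nm]]]][idx], p$fs)[stats_use]
        stats::setNames(st, paste0(nm, "_", stats_use))
      }))
    })
    feat <- as.data.frame(do.call(rbind, rows))
    cbind(data.frame(subject_id = p$subject_id, env_id = p$env_id,
                     window_start_s = ch$t_s[starts],
                     label = ch$label[starts], stringsAsFactors = FALSE),
          feat)
  })
  df <- .rbind_tables(parts)
  feat <- setdiff(names(df), .META_COLS)
  .as_feature_table(df, stats::setNames(rep("ACC", length(feat)), feat))
}

#' Write a feature table to CSV with a sidecar sensor-map JSON
#'
#' @param table A `feature_table`.
#' @param path CSV path; the sensor map goes to `<path>.sensors.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  data.table::fwrite(as.data.frame(table), path)
  writeLines(jsonlite::toJSON(as.list(sensor_map(table)), auto_unbox = TRUE,
                              pretty = TRUE),
             paste0(path, ".sensors.json"))
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  sm <- unlist(jsonlite::fromJSON(paste0(path, ".sensors.json")))
  .as_feature_table(df, sm)
}
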