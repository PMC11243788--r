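#' Multichannel sEMG recording
#'
#' Container for a multichannel surface-EMG time series sampled at a fixed
#' rate. Samples are stored as a time-by-channel numeric matrix; the time base
#' is implicit (`t0 + (i - 1) / rate_hz` for row `i`).
#'
#' @param samples Numeric matrix, time in rows and channels in columns, or a
#'   vector for a single channel.
#' @param rate_hz Sampling frequency in Hz (> 0).
#' @param channels Character vector of unique channel names; defaults to the
#'   column names of `samples`.
#' @param t0 Time of the first sample in seconds.
#' @param conditioned Logical flag marking the recording as the output of the
#'   conditioning chain (see [condition_emg()]).
#' @return An object of class `"emg_recording"`.
#' @seealso [read_timeseries()], [condition_emg()]
#' @export
emg_recording <- function(samples, rate_hz, channels = colnames(samples),
                          t0 = 0, conditioned = FALSE) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("'samples' must be numeric")
  if (is.null(channels)) stop("channel names are required")
  channels <- as.character(channels)
  if (ncol(samples) != length(channels))
    stop("number of channels does not match 'samples' columns")
  if (ncol(samples) < 1L) stop("at least one channel is required")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("'rate_hz' must be a single positive number")
  colnames(samples) <- channels
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         channels = channels, t0 = as.numeric(t0),
         conditioned = isTRUE(conditioned)),
    class = "emg_recording"
  )
}

#' Knee-angle time series
#'
#' @param values Numeric vector of knee flexion angles in degrees (finite).
#' @param rate_hz Sampling frequency in Hz (> 0).
#' @param convention Label describing the sign/zero convention; the default
#'   marks flexion as positive with 0 at full extension.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `"angle_series"`.
#' @export
angle_series <- function(values, rate_hz, convention = "flexion-positive",
                         t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("'values' must be non-empty")
  if (any(!is.finite(values))) stop("'values' must be finite")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("'rate_hz' must be a single positive number")
  structure(
    list(values = values, rate_hz = as.numeric(rate_hz),
         convention = as.character(convention), t0 = as.numeric(t0)),
    class = "angle_series"
  )
}

#' Gait event list
#'
#' Ordered foot-contact (and other) events. Times must be strictly increasing
#' within each side.
#'
#' @param time_s Numeric event times in seconds.
#' @param side Character side labels (e.g. `"right"`, `"left"`).
#' @param event Character event labels; the vocabulary contains at least
#'   `"foot_contact"`.
#' @return A `data.frame` of class `"event_list"` with columns `time_s`,
#'   `side`, `event`.
#' @export
event_list <- function(time_s, side, event = "foot_contact") {
  df <- data.frame(time_s = as.numeric(time_s), side = as.character(side),
                   event = as.character(event), stringsAsFactors = FALSE)
  for (s in unique(df$side)) {
    ts <- df$time_s[df$side == s]
    if (any(diff(ts) <= 0))
      stop("event times must be strictly increasing within side '", s, "'")
  }
  class(df) <- c("event_list", "data.frame")
  df
}

sample_times <- function(x) {
  n <- if (inherits(x, "emg_recording")) nrow(x$samples) else length(x$values)
  x$t0 + (seq_len(n) - 1L) / x$rate_hz
}

#' Read a time-series CSV file
#'
#' Files are comma-delimited UTF-8 text with one header row: `time_s` followed
#' by channel names. The sampling rate is inferred from the median time step;
#' a declared `expected_rate` must agree with the inferred rate within 1%.
#'
#' @param path Path to the CSV file.
#' @param expected_rate Declared sampling rate in Hz, or `NULL` to infer.
#' @param as One of `"auto"`, `"emg"`, `"angle"`. Under `"auto"` a file with a
#'   single data column named `angle` is returned as an [angle_series()],
#'   anything else as an [emg_recording()].
#' @return An `emg_recording` or `angle_series`.
#' @export
read_timeseries <- function(path, expected_rate = NULL,
                            as = c("auto", "emg", "angle")) {
  as <- match.arg(as)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "time_s")
    stop("format error: header must be 'time_s,<ch1>,...' in ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  tm <- df[[1]]
  if (any(diff(tm) <= 0))
    stop("format error: non-monotone time column in ", path)
  steps <- diff(tm)
  rate <- 1 / stats::median(steps)
  if (!is.null(expected_rate)) {
    if (abs(rate - expected_rate) / expected_rate > 0.01)
      stop("rate error: declared ", expected_rate, " Hz but inferred ",
           signif(rate, 6), " Hz in ", path)
    rate <- expected_rate
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  chans <- header[-1]
  if (as == "angle" || (as == "auto" && length(chans) == 1L && chans == "angle"))
    angle_series(vals[, 1], rate, t0 = tm[1])
  else
    emg_recording(vals, rate, channels = chans, t0 = tm[1])
}

#' Write a time series to CSV
#'
#' Values are written with 12 significant digits so that a read/write round
#' trip preserves them to better than 1e-9 absolute for signals of
#' physiological magnitude.
#'
#' @param x An [emg_recording()] or [angle_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  if (inherits(x, "emg_recording")) {
    mat <- x$samples
    header <- c("time_s", x$channels)
  } else if (inherits(x, "angle_series")) {
    mat <- matrix(x$values, ncol = 1L)
    header <- c("time_s", "angle")
  } else stop("'x' must be an emg_recording or angle_series")
  if (ncol(mat) < 1L) stop("empty channel list")
  tm <- sample_times(x)
  body <- cbind(sprintf("%.12g", tm),
                matrix(sprintf("%.12g", mat), nrow = nrow(mat)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read / write gait event CSV files
#'
#' Events use the header `time_s,side,event`.
#'
#' @param path File path.
#' @return [read_events()] returns an [event_list()].
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c("numeric", "character", "character"))
  if (!identical(names(df), c("time_s", "side", "event")))
    stop("format error: events header must be 'time_s,side,event' in ", path)
  event_list(df$time_s, df$side, df$event)
}

#' @rdname read_events
#' @param events An [event_list()].
#' @export
write_events <- function(events, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("time_s,side,event", con)
  writeLines(sprintf("%.12g,%s,%s", events$time_s, events$side, events$event),
             con)
  invisible(path)
}

#' Dataset manifest
#'
#' A manifest is a small structured-text (YAML) file naming the EMG, angle and
#' event files of one trial together with channel list, rates and identifiers.
#'
#' @param path Manifest file path.
#' @return A named list with at least `emg`, `angle`, `events`, `channels`,
#'   `rate_emg`, `rate_angle`.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  req <- c("emg", "angle", "events", "channels", "rate_emg", "rate_angle")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("manifest missing fields: ", paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (f in c("emg", "angle", "events")) {
    p <- m[[f]]
    if (!file.exists(p)) p <- file.path(base, m[[f]])
    if (!file.exists(p)) stop("manifest references missing file: ", m[[f]])
    m[[f]] <- p
  }
  header <- strsplit(readLines(m$emg, n = 1L), ",", fixed = TRUE)[[1]]
  if (!all(m$channels %in% header[-1]))
    stop("manifest channels not all present in EMG file header")
  m
}

#' @rdname read_manifest
#' @param manifest Named list of manifest fields.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Trim EMG and angle streams to their common time window
#'
#' The two streams may be sampled at different rates (EMG typically 1000-2000
#' Hz, kinematics 100 Hz); no resampling happens here -- cycle-level time
#' normalization is done later by [time_normalize()]. The operation is
#' idempotent.
#'
#' @param emg An [emg_recording()].
#' @param angle An [angle_series()].
#' @return A list with elements `emg` and `angle` trimmed to the common
#'   window, plus `start_s` / `end_s` annotations.
#' @export
align_streams <- function(emg, angle, tol = 1e-9) {
  te <- sample_times(emg)
  ta <- sample_times(angle)
  start <- max(te[1], ta[1])
  end <- min(te[length(te)], ta[length(ta)])
  if (start > end + tol)
    stop("alignment error: streams have no overlapping time support")
  keep_e <- te >= start - tol & te <= end + tol
  keep_a <- ta >= start - tol & ta <= end + tol
  emg2 <- emg_recording(emg$samples[keep_e, , drop = FALSE], emg$rate_hz,
                        emg$channels, t0 = te[keep_e][1],
                        conditioned = emg$conditioned)
  ang2 <- angle_series(angle$values[keep_a], angle$rate_hz,
                       convention = angle$convention, t0 = ta[keep_a][1])
  list(emg = emg2, angle = ang2, start_s = start, end_s = end)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("sEMG recording: %d channels x %d samples @ %g Hz (%.2f s)%s\n",
              length(x$channels), nrow(x$samples), x$rate_hz,
              nrow(x$samples) / x$rate_hz,
              if (x$conditioned) ", conditioned" else ""))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("knee-angle series: %d samples @ %g Hz, range [%.1f, %.1f] deg (%s)\n",
              length(x$values), x$rate_hz, min(x$values), max(x$values),
              x$convention))
  invisible(x)
}
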