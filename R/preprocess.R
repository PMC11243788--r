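# Multi-stage sEMG conditioning chain:
# Hampel -> band-pass -> rectification -> peak/RMS envelope -> low-pass.
# All sliding windows are truncated at the signal edges so every stage
# preserves length.

# centered window bounds: lo samples to the left, hi to the right
win_bounds <- function(window) {
  c(lo = floor((window - 1) / 2), hi = floor(window / 2))
}

# truncated-window moving average via cumulative sums
roll_mean_trunc <- function(x, window) {
  n <- length(x)
  b <- win_bounds(window)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  upper <- pmin(i + b[["hi"]], n)
  lower <- pmax(i - b[["lo"]], 1L)
  tot <- cs[upper + 1L] - cs[lower]
  unname(tot / (upper - lower + 1L))
}

# truncated-window moving maximum via shifted pmax
roll_max_trunc <- function(x, window) {
  n <- length(x)
  b <- win_bounds(window)
  out <- rep(-Inf, n)
  for (k in seq.int(-b["lo"], b["hi"])) {
    src <- seq_len(n) + k
    ok <- src >= 1L & src <= n
    out[ok] <- pmax(out[ok], x[src[ok]])
  }
  out
}

#' Hampel filter for outlier removal
#'
#' Replaces sample i by its local median whenever it deviates from that median
#' by more than `nsigma` robust standard deviations (1.4826 x MAD) computed
#' over a centered window of `window` samples per side. Windows are truncated
#' at the edges. The threshold is `nsigma * 1.4826 * MAD`: in a zero-MAD
#' window any nonzero deviation is repaired (an isolated spike amid identical
#' samples is the clearest outlier there is), a constant stretch passes
#' unchanged, and `nsigma = Inf` makes the filter the identity.
#'
#' @param x Numeric signal.
#' @param window Samples per side of the centered window (default 20).
#' @param nsigma Outlier threshold in robust standard deviations.
#' @return Filtered signal, same length as `x`.
#' @export
hampel_filter <- function(x, window = 20, nsigma = 3) {
  n <- length(x)
  if (n == 0L) stop("empty signal")
  if (window < 1) stop("'window' must be >= 1")
  window <- as.integer(window)
  med_of <- function(s, m) {
    # s already sorted
    if (m %% 2L == 1L) s[(m + 1L) %/% 2L] else (s[m %/% 2L] + s[m %/% 2L + 1L]) / 2
  }
  out <- x
  for (i in seq_len(n)) {
    lo <- if (i > window) i - window else 1L
    hi <- if (i + window < n) i + window else n
    w <- x[lo:hi]
    m <- hi - lo + 1L
    med <- med_of(sort.int(w, method = "quick"), m)
    thr <- nsigma * 1.4826 * med_of(sort.int(abs(w - med), method = "quick"), m)
    if (is.finite(thr) && abs(x[i] - med) > thr) out[i] <- med
  }
  out
}

# zero-phase filtering with odd-reflection padding at both ends, so edge
# transients decay inside the padding instead of corrupting the signal
filtfilt_pad <- function(bf, x, npad) {
  n <- length(x)
  if (n < 4L) return(as.numeric(signal::filtfilt(bf, x)))
  npad <- min(n - 1L, npad)
  head_pad <- 2 * x[1] - x[(npad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  as.numeric(y[(npad + 1L):(npad + n)])
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) filtering preserves envelope timing, which
#' matters because the EMG-angle lag is itself informative.
#'
#' @param x Numeric signal.
#' @param rate_hz Sampling rate in Hz.
#' @param low,high Pass-band corner frequencies in Hz (defaults 50 and 190).
#' @param order Butterworth design order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, rate_hz, low = 50, high = 190, order = 4) {
  nyq <- rate_hz / 2
  if (!(low > 0 && low < high)) stop("require 0 < low < high")
  if (high >= nyq) stop("parameter error: 'high' must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filtfilt_pad(bf, x, npad = ceiling(3 * rate_hz / low))
}

#' Full-wave rectification with sliding-window smoothing
#'
#' Absolute value followed by a centered moving average of `window` samples
#' (truncated at the edges). Output is nonnegative and length-preserving.
#'
#' @param x Numeric signal.
#' @param window Moving-average length in samples (default 50).
#' @return Rectified, smoothed signal.
#' @export
rectify <- function(x, window = 50) {
  if (window < 1) stop("'window' must be >= 1")
  roll_mean_trunc(abs(x), window)
}

#' Consecutive peak and RMS envelope detectors
#'
#' Applies a sliding-window maximum (peak detector) followed by a
#' sliding-window RMS over the same window length, in that order. Both
#' windows are centered and truncated at the edges.
#'
#' @param x Nonnegative (rectified) signal.
#' @param window Window length in samples.
#' @return Envelope, same length as `x`.
#' @export
emg_envelope <- function(x, window = 100) {
  if (window < 1) stop("'window' must be >= 1")
  pk <- roll_max_trunc(x, window)
  sqrt(roll_mean_trunc(pk^2, window))
}

#' Zero-phase Butterworth low-pass smoother
#'
#' @param x Numeric signal.
#' @param rate_hz Sampling rate in Hz.
#' @param cut Cutoff frequency in Hz (default 6, a typical linear-envelope
#'   cutoff).
#' @param order Butterworth design order.
#' @return Smoothed signal.
#' @export
lowpass_smooth <- function(x, rate_hz, cut = 6, order = 4) {
  nyq <- rate_hz / 2
  if (cut >= nyq) stop("parameter error: 'cut' must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, cut / nyq, type = "low")
  filtfilt_pad(bf, x, npad = ceiling(3 * rate_hz / cut))
}

#' Conditioning-chain configuration
#'
#' Bundles the parameters of the five-stage chain. Defaults: Hampel window 20
#' samples per side, 50-190 Hz band-pass, 50-sample rectification window,
#' 150-sample envelope window, 6 Hz low-pass (calibrated on synthetic
#' fixtures for envelope recovery; see the methods vignette).
#'
#' @param hampel_window Hampel half-width in samples.
#' @param hampel_nsigma Hampel threshold multiplier.
#' @param band_low,band_high Band-pass corners in Hz.
#' @param band_order Band-pass Butterworth order.
#' @param rectify_window Rectification moving-average window (samples).
#' @param envelope_window Peak/RMS envelope window (samples).
#' @param lowpass_cut Low-pass cutoff in Hz.
#' @param lowpass_order Low-pass Butterworth order.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(hampel_window = 20, hampel_nsigma = 3,
                          band_low = 50, band_high = 190, band_order = 4,
                          rectify_window = 50, envelope_window = 150,
                          lowpass_cut = 6, lowpass_order = 4) {
  if (!(band_low > 0 && band_low < band_high)) stop("require 0 < band_low < band_high")
  stopifnot(hampel_window >= 1, rectify_window >= 1, envelope_window >= 1)
  structure(list(hampel_window = hampel_window, hampel_nsigma = hampel_nsigma,
                 band_low = band_low, band_high = band_high,
                 band_order = band_order, rectify_window = rectify_window,
                 envelope_window = envelope_window, lowpass_cut = lowpass_cut,
                 lowpass_order = lowpass_order),
            class = "filter_config")
}

#' Condition a multichannel sEMG recording
#'
#' Applies, per channel and in this order: Hampel outlier removal, zero-phase
#' band-pass, full-wave rectification with moving-average smoothing,
#' consecutive peak and RMS envelope detection, and zero-phase low-pass
#' smoothing. The result is the linear envelope used as model input.
#'
#' @param recording An [emg_recording()].
#' @param cfg A [filter_config()].
#' @return An `emg_recording` flagged as conditioned.
#' @export
condition_emg <- function(recording, cfg = filter_config()) {
  stopifnot(inherits(recording, "emg_recording"))
  if (cfg$band_high >= recording$rate_hz / 2)
    stop("parameter error: band_high must be below Nyquist")
  out <- apply(recording$samples, 2L, function(x) {
    x <- hampel_filter(x, cfg$hampel_window, cfg$hampel_nsigma)
    x <- bandpass_filter(x, recording$rate_hz, cfg$band_low, cfg$band_high,
                         cfg$band_order)
    x <- rectify(x, cfg$rectify_window)
    x <- emg_envelope(x, cfg$envelope_window)
    # the low-pass can ring slightly below zero on a nonnegative envelope;
    # clamp so the conditioned output stays a physical (nonnegative) envelope
    pmax(0, lowpass_smooth(x, recording$rate_hz, cfg$lowpass_cut,
                           cfg$lowpass_order))
  })
  emg_recording(out, recording$rate_hz, recording$channels, t0 = recording$t0,
                conditioned = TRUE)
}
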