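# Physiologically structured synthetic gait sEMG + knee-angle generator.
#
# Each stride draws a speed and step length from the preset's spatiotemporal
# distribution (stride duration = 2 * step / speed) and per-channel activation
# gains jittered around their nominal values. Channel envelopes are sums of
# wrapped Gaussian activation bursts at standard gait timings; raw EMG is the
# envelope amplitude-modulating a band-limited (60-180 Hz) zero-mean carrier
# plus a white noise floor, so the 50-190 Hz conditioning chain is exercised
# meaningfully. The knee angle is the cycle template plus a fixed linear map
# of lagged envelope deviations (EMG leads motion by ~40 ms), so the EMG
# genuinely carries stride-specific information about the angle and channel
# ablation has a known ground truth.

#' Gait profile (spatiotemporal + knee-angle template parameters)
#'
#' @param step_mean,step_sd Step length mean/SD in metres.
#' @param speed_mean,speed_sd Gait speed mean/SD in m/s.
#' @param baseline Baseline knee flexion offset in degrees.
#' @param stance_peak,swing_peak Peak flexion of the stance and swing waves in
#'   degrees (absolute, including the baseline).
#' @param stance_time,swing_time Peak timings as cycle fractions.
#' @param stance_width,swing_width Gaussian widths as cycle fractions.
#' @return A list of class `"gait_profile"`.
#' @export
gait_profile <- function(step_mean, step_sd, speed_mean, speed_sd,
                         baseline = 5, stance_peak = 20, swing_peak = 62,
                         stance_time = 0.15, swing_time = 0.72,
                         stance_width = 0.07, swing_width = 0.09) {
  stopifnot(step_mean > 0, speed_mean > 0)
  structure(list(step_mean = step_mean, step_sd = step_sd,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 baseline = baseline, stance_peak = stance_peak,
                 swing_peak = swing_peak, stance_time = stance_time,
                 swing_time = swing_time, stance_width = stance_width,
                 swing_width = swing_width),
            class = "gait_profile")
}

#' Muscle activation template
#'
#' Describes per-channel activation bursts (centers and widths as cycle
#' fractions), nominal gains, the coupling weights that map lagged envelope
#' deviations into the knee angle, the carrier band and noise floor.
#'
#' @param channels Channel names.
#' @param bursts Named list; per channel a list with `centers` and `widths`
#'   (cycle fractions in `[0, 1)`).
#' @param gains Named nonnegative nominal gains (arbitrary EMG units).
#' @param weights Named coupling weights in degrees per unit relative gain
#'   deviation.
#' @param carrier_band Carrier pass band in Hz.
#' @param noise_floor White-noise floor amplitude (EMG units).
#' @param act_floor Tonic activation floor added to every envelope.
#' @param gain_jitter SD of the per-stride relative gain jitter.
#' @param lag_s EMG-to-angle lead time in seconds.
#' @param angle_noise_sd Measurement noise SD on the angle, degrees.
#' @return A list of class `"muscle_template"`.
#' @export
muscle_template <- function(channels, bursts, gains, weights,
                            carrier_band = c(60, 180), noise_floor = 0.03,
                            act_floor = 0.05, gain_jitter = 0.2,
                            lag_s = 0.04, angle_noise_sd = 0.3) {
  stopifnot(all(channels %in% names(bursts)),
            all(channels %in% names(gains)),
            all(channels %in% names(weights)),
            all(unlist(gains) >= 0))
  for (ch in channels) {
    ctr <- bursts[[ch]]$centers
    stopifnot(all(ctr >= 0 & ctr < 1))
  }
  structure(list(channels = channels, bursts = bursts, gains = gains,
                 weights = weights, carrier_band = carrier_band,
                 noise_floor = noise_floor, act_floor = act_floor,
                 gain_jitter = gain_jitter, lag_s = lag_s,
                 angle_noise_sd = angle_noise_sd),
            class = "muscle_template")
}

# wrapped sum-of-Gaussians on the unit cycle, peak height 1 per burst group
burst_shape <- function(u, centers, widths) {
  out <- numeric(length(u))
  for (i in seq_along(centers)) {
    for (k in -1:1) {
      out <- out + exp(-0.5 * ((u - centers[i] + k) / widths[i])^2)
    }
  }
  out / max(out[order(u)])  # normalize peak to 1 on the evaluated grid
}

# continuous template function of cycle fraction u
angle_template_fun <- function(profile) {
  function(u) {
    g <- function(c0, w) {
      s <- numeric(length(u))
      for (k in -1:1) s <- s + exp(-0.5 * ((u - c0 + k) / w)^2)
      s
    }
    profile$baseline +
      (profile$stance_peak - profile$baseline) * g(profile$stance_time,
                                                   profile$stance_width) +
      (profile$swing_peak - profile$baseline) * g(profile$swing_time,
                                                  profile$swing_width)
  }
}

#' Knee-angle cycle template
#'
#' Smooth sum-of-Gaussian-bumps trajectory over one normalized gait cycle:
#' a baseline flexion offset, a small stance-flexion wave and a large
#' swing-flexion wave. Bumps are wrapped so the endpoints are periodic.
#'
#' @param profile A [gait_profile()].
#' @param L Number of samples over the cycle.
#' @return Numeric vector of length `L`, degrees.
#' @export
knee_angle_template <- function(profile, L = 100) {
  u <- (seq_len(L) - 1) / L
  angle_template_fun(profile)(u)
}

#' Named synthesis presets
#'
#' * `"hv8"`: 8-channel healthy-adolescent walking (TA, MG, SL, PL, HL, RF,
#'   VL, MH) at 1000 Hz EMG / 100 Hz kinematics, self-selected pace
#'   (speed 0.91 +/- 0.04 m/s, step 0.52 +/- 0.02 m).
#' * `"shared6"`: the 6-channel subset (TA, MG, SL, VL, RF, MH) shared with
#'   the open-source locomotion dataset scenario.
#' * `"cp6"`: 6-channel crouch-gait variant at 2000 Hz EMG with a high noise
#'   floor, large stride variability and slow, visit-dependent speeds
#'   (V1 0.14, V2 0.37, V3 0.52 m/s); the semitendinosus channel is mapped to
#'   the shared-set MH label.
#'
#' Burst timings follow standard gait electromyography (TA active at contact
#' and through swing, MG/SL in late stance, RF/VL at loading response and
#' pre-swing, MH in terminal swing). The knee flexor/extensor channels RF,
#' MG, TA and VL carry the largest angle-coupling weights, so sensitivity
#' analyses have a known ground truth.
#'
#' @param name One of `"hv8"`, `"shared6"`, `"cp6"`.
#' @param visit Visit number 1-3, used by `"cp6"` only.
#' @return A list with `name`, `channels`, `profile`, `template`, `rate_emg`,
#'   `rate_angle`.
#' @export
gait_presets <- function(name = c("hv8", "shared6", "cp6"), visit = 1) {
  name <- match.arg(name)
  bursts <- list(
    TA = list(centers = c(0.02, 0.80), widths = c(0.05, 0.12)),
    MG = list(centers = 0.40, widths = 0.08),
    SL = list(centers = 0.42, widths = 0.08),
    PL = list(centers = 0.35, widths = 0.10),
    HL = list(centers = 0.45, widths = 0.08),
    RF = list(centers = c(0.08, 0.60), widths = c(0.06, 0.07)),
    VL = list(centers = 0.10, widths = 0.07),
    MH = list(centers = c(0.95, 0.03), widths = c(0.06, 0.05)))
  gains <- c(TA = 1, MG = 1, SL = 0.9, PL = 0.7, HL = 0.6, RF = 1,
             VL = 1, MH = 0.8)
  weights <- c(TA = 6, MG = 8, SL = 2, PL = 1, HL = 1, RF = 12, VL = 5,
               MH = 3)
  ch8 <- c("TA", "MG", "SL", "PL", "HL", "RF", "VL", "MH")
  ch6 <- c("TA", "MG", "SL", "VL", "RF", "MH")
  if (name == "hv8") {
    channels <- ch8
    profile <- gait_profile(0.52, 0.02, 0.91, 0.04)
    tmpl <- muscle_template(channels, bursts[channels], gains[channels],
                            weights[channels])
    rate_emg <- 1000
  } else if (name == "shared6") {
    channels <- ch6
    profile <- gait_profile(0.52, 0.02, 0.91, 0.04)
    tmpl <- muscle_template(channels, bursts[channels], gains[channels],
                            weights[channels])
    rate_emg <- 1000
  } else {
    channels <- ch6
    sp <- switch(visit, `1` = c(0.20, 0.04, 0.14, 0.03),
                 `2` = c(0.19, 0.02, 0.37, 0.16),
                 `3` = c(0.17, 0.04, 0.52, 0.06))
    if (is.null(sp)) stop("'visit' must be 1, 2 or 3")
    profile <- gait_profile(sp[1], sp[2], sp[3], sp[4],
                            baseline = 32, stance_peak = 45, swing_peak = 62,
                            stance_time = 0.20, swing_time = 0.75,
                            stance_width = 0.10, swing_width = 0.10)
    tmpl <- muscle_template(channels, bursts[channels], gains[channels],
                            weights[channels], noise_floor = 0.25,
                            gain_jitter = 0.35, angle_noise_sd = 0.8)
    rate_emg <- 2000
  }
  list(name = name, channels = channels, profile = profile, template = tmpl,
       rate_emg = rate_emg, rate_angle = 100,
       visit = if (name == "cp6") visit else NA_integer_)
}

#' Synthesize one walking trial
#'
#' Generates raw multichannel sEMG, the knee-angle series, foot-contact
#' events and a ground-truth sidecar (envelopes, gains, coupling weights,
#' noise powers), fully determined by `(preset, seed)`.
#'
#' @param preset A preset from [gait_presets()], or a list with `channels`,
#'   `profile`, `template`, `rate_emg`, `rate_angle`.
#' @param n_strides Number of strides (>= 1).
#' @param seed Integer seed.
#' @param rate_emg,rate_angle Sampling rates in Hz (defaults from the preset).
#' @param noise_scale Multiplier on the carrier noise floor (1 = preset level;
#'   0.1 is the "low-noise" condition).
#' @param jitter_scale Multiplier on stride-duration/gain variability.
#' @return An object of class `"synthetic_trial"` with elements `emg`
#'   ([emg_recording()]), `angle` ([angle_series()]), `events`
#'   ([event_list()]) and `truth`.
#' @export
synthesize_trial <- function(preset, n_strides, seed = 1,
                             rate_emg = preset$rate_emg,
                             rate_angle = preset$rate_angle,
                             noise_scale = 1, jitter_scale = 1) {
  stopifnot(n_strides >= 1)
  if (!is.numeric(rate_emg) || rate_emg <= 0 ||
      !is.numeric(rate_angle) || rate_angle <= 0)
    stop("invalid rates")
  profile <- preset$profile
  tmpl <- preset$template
  channels <- preset$channels
  C <- length(channels)
  with_seed(seed, {
    speeds <- pmax(0.05, stats::rnorm(n_strides, profile$speed_mean,
                                      jitter_scale * profile$speed_sd))
    steps <- pmax(0.05, stats::rnorm(n_strides, profile$step_mean,
                                     jitter_scale * profile$step_sd))
    durations <- pmin(4.8, pmax(0.3, 2 * steps / speeds))
    gains <- matrix(0, n_strides, C, dimnames = list(NULL, channels))
    for (ch in channels)
      gains[, ch] <- tmpl$gains[[ch]] *
        pmax(0.2, 1 + jitter_scale * tmpl$gain_jitter * stats::rnorm(n_strides))

    bounds <- c(0, cumsum(durations))
    total <- bounds[n_strides + 1L]

    n_emg <- floor(total * rate_emg)
    te <- (seq_len(n_emg) - 1) / rate_emg
    n_ang <- floor(total * rate_angle)
    ta <- (seq_len(n_ang) - 1) / rate_angle

    stride_of <- function(tt) pmin(n_strides, findInterval(tt, bounds))
    se <- stride_of(te); sa <- stride_of(ta)
    ue <- (te - bounds[se]) / durations[se]
    ua <- (ta - bounds[sa]) / durations[sa]

    ugrid <- (0:999) / 1000
    env <- matrix(0, n_emg, C, dimnames = list(NULL, channels))
    drive <- matrix(0, n_ang, C)
    for (j in seq_len(C)) {
      ch <- channels[j]
      shape_g <- burst_shape(ugrid, tmpl$bursts[[ch]]$centers,
                             tmpl$bursts[[ch]]$widths)
      shape_at <- function(u) shape_g[pmin(1000L, floor(u * 1000) + 1L)]
      env[, j] <- gains[se, ch] * shape_at(ue) + tmpl$act_floor
      lag_frac <- tmpl$lag_s / durations[sa]
      drive[, j] <- (gains[sa, ch] / tmpl$gains[[ch]] - 1) *
        shape_at((ua - lag_frac) %% 1)
    }

    raw <- matrix(0, n_emg, C, dimnames = list(NULL, channels))
    for (j in seq_len(C)) {
      carrier <- bandpass_filter(stats::rnorm(n_emg), rate_emg,
                                 tmpl$carrier_band[1], tmpl$carrier_band[2])
      carrier <- carrier / sqrt(mean(carrier^2))
      raw[, j] <- env[, j] * carrier +
        noise_scale * tmpl$noise_floor * stats::rnorm(n_emg)
    }

    tf <- angle_template_fun(profile)
    w <- unlist(tmpl$weights[channels])
    angle <- tf(ua) + as.numeric(drive %*% w) +
      tmpl$angle_noise_sd * stats::rnorm(n_ang)

    events <- event_list(bounds, side = "right")
    structure(list(
      emg = emg_recording(raw, rate_emg, channels),
      angle = angle_series(angle, rate_angle),
      events = events,
      truth = list(envelopes = env, gains = gains,
                   weights = w, speeds = speeds, steps = steps,
                   durations = durations,
                   noise_power = (noise_scale * tmpl$noise_floor)^2,
                   envelope_power = colMeans(env^2)),
      preset = preset, n_strides = n_strides, seed = seed,
      noise_scale = noise_scale, jitter_scale = jitter_scale),
      class = "synthetic_trial")
  })
}

#' Degrade a trial toward cerebral-palsy signal quality
#'
#' Re-synthesizes the trial (same seed and preset) with the carrier/noise
#' floor raised so that the envelope-to-noise power ratio is scaled by
#' `snr_scale`, and the stride-duration/amplitude variability inflated by
#' `variability_scale`. Identity factors reproduce the input trial exactly.
#'
#' @param trial A [synthesize_trial()] result.
#' @param snr_scale Power-ratio scale factor (> 0); 0.25 reduces the
#'   envelope-to-noise power ratio about 4-fold.
#' @param variability_scale Variability inflation factor (> 0).
#' @param seed Seed (defaults to the trial's own).
#' @return A new `synthetic_trial`.
#' @export
cp_degrade <- function(trial, snr_scale = 1, variability_scale = 1,
                       seed = trial$seed) {
  stopifnot(inherits(trial, "synthetic_trial"), snr_scale > 0,
            variability_scale > 0)
  synthesize_trial(trial$preset, trial$n_strides, seed = seed,
                   noise_scale = trial$noise_scale / sqrt(snr_scale),
                   jitter_scale = trial$jitter_scale * variability_scale)
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("synthetic trial '%s': %d strides, %d channels, %.1f s (seed %d)\n",
              x$preset$name, x$n_strides, length(x$preset$channels),
              nrow(x$emg$samples) / x$emg$rate_hz, x$seed))
  cat(sprintf("  mean speed %.2f m/s, noise_scale %g, jitter_scale %g\n",
              mean(x$truth$speeds), x$noise_scale, x$jitter_scale))
  invisible(x)
}

#' Condition, segment and split a trial into a model-ready dataset
#'
#' Convenience wrapper: conditions the raw EMG with [condition_emg()], aligns
#' the streams, splits them into gait cycles at the trial's foot-contact
#' events, time-normalizes each cycle to `L` samples and assembles the
#' train/test [gait_dataset()].
#'
#' @param trial A `synthetic_trial`, or a list with `emg`, `angle`, `events`.
#' @param cfg A [filter_config()].
#' @param L Normalized cycle length.
#' @param side Side label.
#' @param train_frac Training fraction.
#' @return A [gait_dataset()].
#' @export
prepare_dataset <- function(trial, cfg = filter_config(), L = 100,
                            side = "right", train_frac = 0.6) {
  cond <- condition_emg(trial$emg, cfg)
  al <- align_streams(cond, trial$angle)
  cycles <- split_cycles(al$emg, al$angle, trial$events, side = side)
  gait_dataset(cycles, train_frac = train_frac, L = L)
}
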