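# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

# small healthy trial + model-ready dataset (8 channels, 8 strides)
fix_trial <- synthesize_trial(gait_presets("hv8"), n_strides = 8, seed = 3)
fix_ds <- prepare_dataset(fix_trial)

# hand-built normalized gait cycles on a known smooth mapping, bypassing the
# conditioning chain (fast path for model-level tests).
# Channel envelopes are Gaussian bumps with per-stride gains; the angle is an
# affine function of the (lagged-free) first channel's envelope.
make_cycles <- function(n, channels = c("TA", "RF"), L = 100, seed = 1,
                        gain_sd = 0.05, angle_fun = NULL) {
  u <- (seq_len(L) - 1) / (L - 1)
  shapes <- list(
    exp(-0.5 * ((u - 0.3) / 0.1)^2),
    exp(-0.5 * ((u - 0.7) / 0.1)^2),
    exp(-0.5 * ((u - 0.5) / 0.15)^2),
    exp(-0.5 * ((u - 0.15) / 0.07)^2))
  if (is.null(angle_fun))
    angle_fun <- function(emg) 10 + 50 * emg[, 1]
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    emg <- vapply(seq_along(channels), function(j) {
      g <- 1 + gain_sd * rnorm(1)
      g * shapes[[(j - 1) %% length(shapes) + 1]]
    }, numeric(L))
    colnames(emg) <- channels
    structure(list(start_s = i - 1, end_s = i,
                   emg = emg, emg_times = u + i - 1,
                   angle = angle_fun(emg), angle_times = u + i - 1,
                   channels = channels, side = "right",
                   normalized = TRUE, L = as.integer(L)),
              class = "gait_cycle")
  })
}

# quick low-budget training config for tests that just need a fitted model
quick_fit <- function(ds, hidden = 8, max_epochs = 5, seed = 1, ...) {
  gru_am(ds, hidden = hidden, max_epochs = max_epochs, seed = seed, ...)
}
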