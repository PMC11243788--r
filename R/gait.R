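# Gait-cycle extraction, time normalization, segment construction and
# train/test dataset assembly.

#' Split aligned streams into gait cycles
#'
#' A gait cycle spans from one foot-ground contact event to the next contact
#' of the same foot. Cycles shorter than `min_dur` or longer than `max_dur`
#' seconds are discarded with a warning (they are almost always event-detection
#' artifacts).
#'
#' @param emg Conditioned [emg_recording()].
#' @param angle [angle_series()] on the same time base.
#' @param events [event_list()] containing `foot_contact` events.
#' @param side Side label to extract (default `"right"`).
#' @param min_dur,max_dur Admissible cycle duration bounds in seconds.
#' @return A list of `gait_cycle` objects (raw, not yet time-normalized).
#' @export
split_cycles <- function(emg, angle, events, side = "right",
                         min_dur = 0.2, max_dur = 5) {
  fc <- events[events$side == side & events$event == "foot_contact", ]
  if (nrow(fc) < 2L) {
    warning("fewer than 2 foot_contact events for side '", side,
            "'; no cycles extracted")
    return(list())
  }
  te <- sample_times(emg)
  ta <- sample_times(angle)
  cycles <- list()
  dropped <- 0L
  for (k in seq_len(nrow(fc) - 1L)) {
    t_a <- fc$time_s[k]
    t_b <- fc$time_s[k + 1L]
    dur <- t_b - t_a
    if (dur < min_dur || dur > max_dur) { dropped <- dropped + 1L; next }
    ie <- which(te >= t_a & te < t_b)
    ia <- which(ta >= t_a & ta < t_b)
    if (length(ie) < 2L || length(ia) < 2L) { dropped <- dropped + 1L; next }
    cycles[[length(cycles) + 1L]] <- structure(
      list(start_s = t_a, end_s = t_b,
           emg = emg$samples[ie, , drop = FALSE], emg_times = te[ie],
           angle = angle$values[ia], angle_times = ta[ia],
           channels = emg$channels, side = side,
           normalized = FALSE, L = NA_integer_),
      class = "gait_cycle")
  }
  if (dropped > 0L)
    warning(dropped, " cycle(s) discarded (duration outside [",
            min_dur, ", ", max_dur, "] s or too few samples)")
  cycles
}

#' Time-normalize a gait cycle
#'
#' Linearly interpolates every EMG channel and the knee angle onto `L` equally
#' spaced points spanning the cycle, so that all strides share a common
#' normalized time base (percent of gait cycle). Idempotent for an already
#' normalized cycle with the same `L`.
#'
#' @param cycle A `gait_cycle` from [split_cycles()].
#' @param L Normalized length in samples (default 100).
#' @return The normalized `gait_cycle`.
#' @export
time_normalize <- function(cycle, L = 100) {
  stopifnot(inherits(cycle, "gait_cycle"))
  if (cycle$end_s <= cycle$start_s) stop("degenerate (zero-duration) cycle")
  if (isTRUE(cycle$normalized) && identical(cycle$L, as.integer(L)))
    return(cycle)
  grid_e <- seq(cycle$emg_times[1], cycle$emg_times[length(cycle$emg_times)],
                length.out = L)
  grid_a <- seq(cycle$angle_times[1], cycle$angle_times[length(cycle$angle_times)],
                length.out = L)
  emg <- vapply(seq_along(cycle$channels), function(j)
    stats::approx(cycle$emg_times, cycle$emg[, j], xout = grid_e, rule = 2)$y,
    numeric(L))
  colnames(emg) <- cycle$channels
  ang <- stats::approx(cycle$angle_times, cycle$angle, xout = grid_a, rule = 2)$y
  cycle$emg <- emg
  cycle$emg_times <- grid_e
  cycle$angle <- ang
  cycle$angle_times <- grid_a
  cycle$normalized <- TRUE
  cycle$L <- as.integer(L)
  cycle
}

#' Build the encoder segment sequence of a cycle
#'
#' Partitions each channel of a time-normalized cycle into consecutive
#' non-overlapping `window`-sample segments and orders them time-major,
#' channel-minor (the encoder walks the gait cycle chronologically, seeing all
#' channels of one time window before moving on). With `L = 100` and
#' `window = 20` this yields 5 windows per channel: 40 segments for 8 muscles
#' and 30 for 6.
#'
#' @param cycle A normalized `gait_cycle`.
#' @param window Segment length in samples (default 20).
#' @return An object of class `"segment_sequence"`: a list with `segments`
#'   (an M x window matrix, one segment per row), `channels`, `window`, `L`.
#' @export
segment_cycle <- function(cycle, window = 20) {
  stopifnot(inherits(cycle, "gait_cycle"))
  if (!isTRUE(cycle$normalized)) stop("cycle must be time-normalized first")
  L <- cycle$L
  if (L %% window != 0L)
    stop("L = ", L, " is not divisible by window = ", window,
         "; choose L a multiple of the window (e.g. L = ",
         window * ceiling(L / window), ")")
  n_win <- L %/% window
  C <- length(cycle$channels)
  segs <- matrix(0, nrow = n_win * C, ncol = window)
  for (w in seq_len(n_win)) {
    rows <- ((w - 1L) * window + 1L):(w * window)
    for (ch in seq_len(C)) {
      segs[(w - 1L) * C + ch, ] <- cycle$emg[rows, ch]
    }
  }
  structure(list(segments = segs, channels = cycle$channels,
                 window = as.integer(window), L = L),
            class = "segment_sequence")
}

#' Assemble a train/test gait-cycle dataset
#'
#' Normalization statistics (per-channel envelope min/max and angle min/max)
#' are computed on the training cycles only, so no test-set value leaks into
#' the scaling. The split is chronological by default -- the first
#' `floor(train_frac * n)` cycles train, the rest test -- which avoids
#' temporal leakage between adjacent strides; a seeded shuffled mode is
#' available.
#'
#' @param cycles List of `gait_cycle` objects (normalized, or they will be
#'   normalized to `L`).
#' @param train_frac Training fraction in (0, 1); default 0.6.
#' @param L Normalized cycle length.
#' @param shuffle Logical; randomize the split (seeded) instead of the
#'   chronological default.
#' @param seed Seed used only when `shuffle = TRUE`.
#' @return An object of class `"gait_dataset"` with elements `cycles`,
#'   `split` (factor `"train"`/`"test"`), `stats`, `channels`, `L`.
#' @export
gait_dataset <- function(cycles, train_frac = 0.6, L = 100,
                         shuffle = FALSE, seed = 1) {
  if (length(cycles) < 2L) stop("need at least 2 cycles")
  if (!(train_frac > 0 && train_frac < 1))
    stop("parameter error: 'train_frac' must be in (0, 1)")
  cycles <- lapply(cycles, time_normalize, L = L)
  chans <- cycles[[1]]$channels
  for (cy in cycles)
    if (!identical(cy$channels, chans)) stop("cycles disagree on channels")
  n <- length(cycles)
  n_train <- floor(train_frac * n)
  if (n_train < 1L || n_train >= n) stop("split leaves an empty train or test set")
  idx <- seq_len(n)
  if (shuffle) idx <- with_seed(seed, sample(idx))
  split <- factor(rep("test", n), levels = c("train", "test"))
  split[idx[seq_len(n_train)]] <- "train"
  tr <- cycles[split == "train"]
  emg_tr <- do.call(rbind, lapply(tr, `[[`, "emg"))
  ang_tr <- unlist(lapply(tr, `[[`, "angle"))
  stats <- list(emg_min = apply(emg_tr, 2L, min),
                emg_max = apply(emg_tr, 2L, max),
                angle_min = min(ang_tr), angle_max = max(ang_tr))
  structure(list(cycles = cycles, split = split, stats = stats,
                 channels = chans, L = cycles[[1]]$L),
            class = "gait_dataset")
}

#' Remove one channel from a gait dataset
#'
#' Used by the ablation protocol: drops the channel from every cycle and from
#' the (train-only) normalization statistics; the angle scaling is untouched.
#'
#' @param dataset A [gait_dataset()].
#' @param channel Channel name to remove.
#' @return The reduced `gait_dataset`.
#' @export
drop_channel <- function(dataset, channel) {
  stopifnot(inherits(dataset, "gait_dataset"))
  j <- match(channel, dataset$channels)
  if (is.na(j)) stop("no such channel: ", channel)
  if (length(dataset$channels) < 2L) stop("cannot drop the only channel")
  dataset$channels <- dataset$channels[-j]
  dataset$cycles <- lapply(dataset$cycles, function(cy) {
    cy$emg <- cy$emg[, -j, drop = FALSE]
    cy$channels <- cy$channels[-j]
    cy
  })
  dataset$stats$emg_min <- dataset$stats$emg_min[-j]
  dataset$stats$emg_max <- dataset$stats$emg_max[-j]
  dataset
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("gait dataset: %d cycles (%d train / %d test), %d channels, L = %d\n",
              length(x$cycles), sum(x$split == "train"), sum(x$split == "test"),
              length(x$channels), x$L))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat(sprintf("  angle range (train): [%.1f, %.1f] deg\n",
              x$stats$angle_min, x$stats$angle_max))
  invisible(x)
}

#' @export
print.segment_sequence <- function(x, ...) {
  cat(sprintf("segment sequence: %d segments of %d samples (%d channels, L = %d)\n",
              nrow(x$segments), x$window, length(x$channels), x$L))
  invisible(x)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
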