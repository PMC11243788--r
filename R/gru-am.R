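# User-facing estimator: encoder-decoder GRU with Bahdanau attention.

#' Bahdanau alignment score
#'
#' Computes `Va' tanh(Ua s_prev + Wa h_j)`, the (scalar) alignment between the
#' previous decoder hidden state and one encoder hidden state.
#'
#' @param params List with elements `Va` (length-H vector), `Ua`, `Wa`
#'   (H x H matrices).
#' @param s_prev Previous decoder hidden state (length H).
#' @param h_j One encoder hidden state (length H).
#' @return A scalar score.
#' @export
alignment_score <- function(params, s_prev, h_j) {
  s_prev <- as.numeric(s_prev); h_j <- as.numeric(h_j)
  H <- length(params$Va)
  if (length(s_prev) != ncol(params$Ua) || length(h_j) != ncol(params$Wa) ||
      nrow(params$Ua) != H || nrow(params$Wa) != H)
    stop("dimension mismatch between attention parameters and states")
  sum(params$Va * tanh(params$Ua %*% s_prev + params$Wa %*% h_j))
}

#' Attention weights (softmax over alignment scores)
#'
#' @param scores Numeric vector of alignment scores over encoder steps.
#' @return Weights that are positive and sum to 1.
#' @export
attention_weights <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 1L) stop("need at least one score")
  if (any(!is.finite(scores))) stop("non-finite alignment score")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Attention context vector
#'
#' Weighted sum of encoder hidden states, `c = sum_j alpha_j h_j`.
#'
#' @param weights Attention weights (length M).
#' @param states Encoder hidden states: an M x H matrix (one state per row) or
#'   a list of length-H vectors.
#' @return A length-H context vector.
#' @export
context_vector <- function(weights, states) {
  if (is.list(states)) states <- do.call(rbind, states)
  if (length(weights) != nrow(states))
    stop("length of 'weights' must match the number of encoder states")
  as.numeric(crossprod(states, weights))
}

#' Fit a GRU knee-angle estimator with (or without) Bahdanau attention
#'
#' Trains an encoder-decoder recurrent network mapping the segment sequence of
#' each gait cycle (20-sample EMG-envelope segments, time-major) to the
#' knee-angle trajectory over the cycle. The encoder is a single-layer GRU
#' read once per segment; the decoder is a single-layer GRU emitting one
#' normalized angle sample per step through a sigmoid output, with Bahdanau
#' attention over all encoder states (or, for the attention-free baseline,
#' the final encoder state as a fixed context). Training is full-batch ADAM
#' on min-max-normalized angles with binary cross-entropy by default, the
#' decoder running free (see `teacher_forcing`), and stops when the training
#' RMSE falls below `rmse_stop` degrees or at `max_epochs` epochs.
#'
#' @param data A [gait_dataset()].
#' @param hidden Hidden size of both GRUs (default 100).
#' @param attention Logical; `FALSE` fits the attention-free GRU baseline.
#' @param loss `"bce"` (default) or `"mse"`, applied on the normalized scale.
#' @param lr ADAM learning rate.
#' @param rmse_stop Early-stopping threshold on training RMSE, in degrees
#'   (default 15).
#' @param max_epochs Epoch budget (default 10000).
#' @param window Encoder segment length in samples (default 20).
#' @param seed Seed for the (deterministic) weight initialization.
#' @param teacher_forcing Feed true previous outputs to the decoder during
#'   training instead of its own predictions. Defaults to FALSE: the decoder
#'   is trained exactly as it is deployed (free-running, with gradients
#'   carried through the fed-back prediction), which avoids the exposure
#'   bias a teacher-forced decoder shows at inference.
#' @param verbose Print per-epoch progress.
#' @return An object of class `"gru_am"`.
#' @examples
#' trial <- synthesize_trial(gait_presets("hv8"), n_strides = 6, seed = 1)
#' ds <- prepare_dataset(trial)
#' fit <- gru_am(ds, hidden = 8, max_epochs = 3, seed = 1)
#' fit
#' @export
gru_am <- function(data, hidden = 100, attention = TRUE,
                   loss = c("bce", "mse"), lr = 1e-3, rmse_stop = 15,
                   max_epochs = 10000, window = 20, seed = 1,
                   teacher_forcing = FALSE, verbose = FALSE) {
  stopifnot(inherits(data, "gait_dataset"))
  loss <- match.arg(loss)
  if (rmse_stop <= 0) stop("'rmse_stop' must be positive")
  if (hidden < 1) stop("'hidden' must be >= 1")
  if (data$L %% window != 0L) stop("L must be divisible by 'window'")
  tr <- data$cycles[data$split == "train"]
  if (length(tr) < 1L) stop("empty training set")
  params <- with_seed(seed, init_params(window, hidden, attention))
  model <- structure(
    list(params = params, hidden = hidden, attention = attention,
         loss = loss, lr = lr, rmse_stop = rmse_stop,
         max_epochs = max_epochs, window = window, L = data$L,
         channels = data$channels, stats = data$stats, seed = seed,
         teacher_forcing = teacher_forcing,
         history = data.frame(epoch = integer(), loss = numeric(),
                              rmse = numeric()),
         terminated = "untrained", provenance = "fit"),
    class = "gru_am")
  gru_am_update(model, tr, max_epochs = max_epochs, rmse_stop = rmse_stop,
                verbose = verbose)
}

#' Continue training a fitted estimator on (more) cycles
#'
#' Warm-start training used by the personalization and sequential-learning
#' protocols. The model's normalization statistics are kept fixed (they were
#' set by the original training data), so updates never peek at new scaling
#' information.
#'
#' @param model A `gru_am` object.
#' @param cycles List of normalized `gait_cycle` objects to train on.
#' @param max_epochs Epoch budget for this update.
#' @param rmse_stop Stop when training RMSE (degrees) falls below this.
#' @param verbose Print per-epoch progress.
#' @return The updated `gru_am`.
#' @export
gru_am_update <- function(model, cycles, max_epochs = model$max_epochs,
                          rmse_stop = model$rmse_stop, verbose = FALSE) {
  stopifnot(inherits(model, "gru_am"))
  if (length(cycles) < 1L) stop("empty training set")
  check_channels(model, cycles[[1]])
  tn <- cycles_tensors(cycles, model$stats, model$window)
  params <- model$params
  opt <- adam_init(params)
  hist_e <- integer(0); hist_l <- numeric(0); hist_r <- numeric(0)
  terminated <- if (max_epochs == 0L) "max_epochs" else "untrained"
  arng <- model$stats$angle_max - model$stats$angle_min
  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    fw <- net_forward(params, tn$X, tn$L, Y = tn$Y,
                      teacher = model$teacher_forcing,
                      use_attention = model$attention, keep = TRUE)
    lg <- loss_grad(fw$Yhat, tn$Y, model$loss)
    rmse_deg <- sqrt(mean((fw$Yhat - tn$Y)^2)) * arng
    hist_e <- c(hist_e, epoch); hist_l <- c(hist_l, lg$value)
    hist_r <- c(hist_r, rmse_deg)
    if (verbose)
      message(sprintf("epoch %d: loss %.5f, train RMSE %.2f deg",
                      epoch, lg$value, rmse_deg))
    if (rmse_deg < rmse_stop) { terminated <- "rmse"; break }
    grads <- net_backward(params, fw, tn$X, lg$dO,
                          use_attention = model$attention,
                          teacher = model$teacher_forcing)
    upd <- adam_step(params, grads, opt, lr = model$lr)
    params <- upd$params
    opt <- upd$state
    if (epoch == max_epochs) terminated <- "max_epochs"
  }
  model$params <- params
  model$history <- rbind(model$history,
                         data.frame(epoch = hist_e, loss = hist_l,
                                    rmse = hist_r))
  model$terminated <- terminated
  model
}

check_channels <- function(model, x) {
  chans <- if (inherits(x, "segment_sequence") || inherits(x, "gait_cycle"))
    x$channels else x
  if (!identical(chans, model$channels)) {
    missing <- setdiff(model$channels, chans)
    extra <- setdiff(chans, model$channels)
    stop("channel mismatch: missing [", paste(missing, collapse = ", "),
         "], extra [", paste(extra, collapse = ", "), "]")
  }
  invisible(TRUE)
}

#' Estimate knee-angle trajectories
#'
#' Runs the free-running decoder (no teacher forcing) and de-normalizes the
#' outputs to degrees with the angle bounds stored at training time, so every
#' estimate lies within the training angle range.
#'
#' @param object A fitted `gru_am`.
#' @param newdata A [gait_dataset()] (with `which` selecting the split), a
#'   list of `gait_cycle`s, a single `gait_cycle`, or a
#'   [segment_cycle()] sequence.
#' @param which For a `gait_dataset`: `"test"` (default), `"train"` or
#'   `"all"`.
#' @param ... Unused.
#' @return A matrix of estimated angles in degrees, one row per cycle,
#'   `L` columns.
#' @export
predict.gru_am <- function(object, newdata, which = c("test", "train", "all"),
                           ...) {
  which <- match.arg(which)
  cycles <- NULL
  if (inherits(newdata, "gait_dataset")) {
    cycles <- switch(which,
                     test = newdata$cycles[newdata$split == "test"],
                     train = newdata$cycles[newdata$split == "train"],
                     all = newdata$cycles)
  } else if (inherits(newdata, "gait_cycle")) {
    cycles <- list(newdata)
  } else if (inherits(newdata, "segment_sequence")) {
    check_channels(object, newdata)
    X <- lapply(seq_len(nrow(newdata$segments)), function(m)
      matrix(norm_segment(object, newdata, m), 1L))
    fw <- net_forward(object$params, X, object$L,
                      use_attention = object$attention)
    return(denorm_angle(fw$Yhat, object$stats))
  } else if (is.list(newdata)) {
    cycles <- newdata
  } else stop("unsupported 'newdata'")
  if (length(cycles) == 0L) stop("no cycles to estimate")
  for (cy in cycles) check_channels(object, cy)
  tn <- cycles_tensors(cycles, object$stats, object$window)
  fw <- net_forward(object$params, tn$X, tn$L,
                    use_attention = object$attention)
  denorm_angle(fw$Yhat, object$stats)
}

# normalize one raw segment of a segment_sequence (segments are stored on the
# conditioned-envelope scale; channel index cycles fastest within a window)
norm_segment <- function(model, seq, m) {
  C <- length(seq$channels)
  ch <- ((m - 1L) %% C) + 1L
  norm_channel(seq$segments[m, ], model$stats$emg_min[ch],
               model$stats$emg_max[ch])
}

#' @export
fitted.gru_am <- function(object, data, ...) {
  if (missing(data)) stop("pass the gait_dataset used for fitting as 'data'")
  predict(object, data, which = "train")
}

#' @export
residuals.gru_am <- function(object, data, which = "test", ...) {
  if (missing(data)) stop("pass a gait_dataset as 'data'")
  pred <- predict(object, data, which = which)
  meas <- measured_angles(data, which)
  meas - pred
}

measured_angles <- function(data, which = "test") {
  cycles <- switch(which,
                   test = data$cycles[data$split == "test"],
                   train = data$cycles[data$split == "train"],
                   all = data$cycles)
  do.call(rbind, lapply(cycles, `[[`, "angle"))
}

#' @export
coef.gru_am <- function(object, ...) object$params

#' @export
print.gru_am <- function(x, ...) {
  cat(sprintf("%s knee-angle estimator\n",
              if (x$attention) "GRU-AM (attention)" else "GRU (baseline)"))
  cat(sprintf("  hidden size %d, %d channels, segment window %d, L = %d\n",
              x$hidden, length(x$channels), x$window, x$L))
  cat(sprintf("  %d parameters; loss %s; %d epochs trained (stop: %s)\n",
              n_parameters(x$params), x$loss, nrow(x$history), x$terminated))
  if (nrow(x$history) > 0)
    cat(sprintf("  final training RMSE %.2f deg\n",
                x$history$rmse[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.gru_am <- function(object, data = NULL, ...) {
  out <- list(model = object)
  if (!is.null(data)) {
    pred <- predict(object, data, which = "test")
    meas <- measured_angles(data, "test")
    out$test_metrics <- stride_metrics(meas, pred)
  }
  class(out) <- "summary.gru_am"
  out
}

#' @export
print.summary.gru_am <- function(x, ...) {
  print(x$model)
  if (!is.null(x$test_metrics)) {
    m <- x$test_metrics
    cat(sprintf("  test (n = %d strides): RMSE %.2f +/- %.2f deg, CC %.3f, SNR %.2f dB\n",
                nrow(m), mean(m$rmse), stats::sd(m$rmse), mean(m$cc),
                mean(m$snr)))
  }
  invisible(x)
}

#' Plot training history and an example estimated stride
#'
#' @param x A fitted `gru_am`.
#' @param data Optional [gait_dataset()]; when given, the first test stride is
#'   overlaid with its estimate.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gru_am <- function(x, data = NULL, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(data)) 1 else 2))
  on.exit(graphics::par(op))
  graphics::plot(x$history$epoch, x$history$rmse, type = "l",
                 xlab = "epoch", ylab = "training RMSE (deg)",
                 main = "training history", ...)
  graphics::abline(h = x$rmse_stop, lty = 2, col = "grey40")
  if (!is.null(data)) {
    meas <- measured_angles(data, "test")[1, ]
    pred <- predict(x, data, which = "test")[1, ]
    graphics::plot(seq_along(meas), meas, type = "l", col = "red",
                   xlab = "% gait cycle", ylab = "knee angle (deg)",
                   main = "example test stride",
                   ylim = range(c(meas, pred)))
    graphics::lines(seq_along(pred), pred, col = "black")
    graphics::legend("topleft", c("measured", "estimated"),
                     col = c("red", "black"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Save / load an estimator checkpoint
#'
#' Writes the parameter blob (`params.rds`) plus a plain-text JSON sidecar
#' recording channels, window, normalized length, normalization bounds, seed,
#' configuration and provenance. Loading restores the estimator bit-exactly.
#'
#' @param model A `gru_am`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir` (save) or the restored `gru_am` (load).
#' @export
save_gru_am <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "params.rds"))
  side <- model[setdiff(names(model), c("params", "history"))]
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_gru_am
#' @export
load_gru_am <- function(dir) {
  readRDS(file.path(dir, "params.rds"))
}
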