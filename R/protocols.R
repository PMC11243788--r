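# Experiment protocols: attention-vs-baseline comparison, channel ablation,
# transfer learning with stride-level personalization, sequential (cyclic)
# learning and multi-visit progressive adaptation.

#' Compare the GRU-AM against the attention-free GRU baseline
#'
#' Trains both variants with matched seeds and identical configuration (the
#' attention flag is the only difference between arms) and reports per-seed
#' and mean test RMSE/CC.
#'
#' @param dataset A [gait_dataset()].
#' @param n_seeds Number of matched seeds (default 5).
#' @param seeds Optional explicit seed vector (overrides `n_seeds`).
#' @param ... Passed to [gru_am()] (e.g. `hidden`, `max_epochs`).
#' @return A `data.frame` of class `"model_comparison"` with columns `model`,
#'   `seed`, `rmse`, `cc`.
#' @export
compare_models <- function(dataset, n_seeds = 5, seeds = NULL, ...) {
  if (is.null(seeds)) seeds <- seq_len(n_seeds)
  rows <- list()
  for (s in seeds) {
    for (att in c(TRUE, FALSE)) {
      fit <- gru_am(dataset, attention = att, seed = s, ...)
      pred <- predict(fit, dataset, which = "test")
      meas <- measured_angles(dataset, "test")
      sm <- stride_metrics(meas, pred)
      rows[[length(rows) + 1L]] <- data.frame(
        model = if (att) "GRU-AM" else "GRU", seed = s,
        rmse = mean(sm$rmse), cc = mean(sm$cc))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  agg <- stats::aggregate(cbind(rmse, cc) ~ model, data = x, FUN = mean)
  cat("model comparison (mean over", length(unique(x$seed)), "seeds):\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-7s RMSE %.2f deg, CC %.3f\n", agg$model[i],
                agg$rmse[i], agg$cc[i]))
  invisible(x)
}

#' Channel-ablation sensitivity analysis
#'
#' For each channel, retrains the estimator from scratch (same seed) on the
#' dataset with that channel removed and evaluates on the test strides. The
#' report ranks channels by the RMSE increase over the full model; large
#' increases mark primary contributors to the angle estimate.
#'
#' @param dataset A [gait_dataset()] with at least 2 channels.
#' @param seed Shared training seed.
#' @param ... Passed to [gru_am()].
#' @return A list of class `"ablation_report"` with `full` (full-model mean
#'   RMSE/CC) and `table` (per-channel mean RMSE, CC, `delta_rmse`, ranked).
#' @export
ablate_channels <- function(dataset, seed = 1, ...) {
  if (length(dataset$channels) < 2L)
    stop("ablation needs at least 2 channels")
  meas <- measured_angles(dataset, "test")
  eval_fit <- function(ds) {
    fit <- gru_am(ds, seed = seed, ...)
    sm <- stride_metrics(meas, predict(fit, ds, which = "test"))
    c(rmse = mean(sm$rmse), cc = mean(sm$cc))
  }
  full <- eval_fit(dataset)
  rows <- lapply(dataset$channels, function(ch) {
    m <- eval_fit(drop_channel(dataset, ch))
    data.frame(channel = ch, rmse = m["rmse"], cc = m["cc"],
               delta_rmse = m["rmse"] - full["rmse"], row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$delta_rmse), ]
  tab$rank <- seq_len(nrow(tab))
  structure(list(full = full, table = tab), class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("channel ablation (full model: RMSE %.2f deg, CC %.3f)\n",
              x$full["rmse"], x$full["cc"]))
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %d. -%s: RMSE %.2f (delta %+0.2f), CC %.3f\n",
                x$table$rank[i], x$table$channel[i], x$table$rmse[i],
                x$table$delta_rmse[i], x$table$cc[i]))
  invisible(x)
}

shared6_channels <- c("TA", "MG", "SL", "VL", "RF", "MH")

#' Pretrain an estimator on a source (open-dataset style) population
#'
#' Validates that the source uses exactly the 6-channel shared muscle set
#' (TA, MG, SL, VL, RF, MH) and trains an estimator tagged with source
#' provenance, ready for per-subject personalization.
#'
#' @param source_dataset A [gait_dataset()] over the shared channel set.
#' @param ... Passed to [gru_am()].
#' @return A `gru_am` with `provenance = "source-pretrain"`.
#' @export
pretrain_transfer <- function(source_dataset, ...) {
  if (!setequal(source_dataset$channels, shared6_channels) ||
      length(source_dataset$channels) != 6L)
    stop("transfer pretraining requires the 6-channel shared set: ",
         paste(shared6_channels, collapse = ", "))
  fit <- gru_am(source_dataset, ...)
  fit$provenance <- "source-pretrain"
  fit
}

#' Personalize a pretrained estimator with a few subject strides
#'
#' Warm-starts training on the first `n_strides` cycles of the subject
#' (default 10) under the same termination rule as the original training.
#' `n_strides = 0` returns the model unchanged.
#'
#' @param model A pretrained `gru_am`.
#' @param subject_cycles List of the subject's normalized `gait_cycle`s.
#' @param n_strides Number of leading strides to train on (default 10).
#' @param max_epochs,rmse_stop Termination rule for the personalization.
#' @return The personalized `gru_am`.
#' @export
personalize <- function(model, subject_cycles, n_strides = 10,
                        max_epochs = model$max_epochs,
                        rmse_stop = model$rmse_stop) {
  if (n_strides == 0L) return(model)
  if (n_strides > length(subject_cycles))
    stop("insufficient cycles: ", length(subject_cycles), " available, ",
         n_strides, " requested")
  model <- gru_am_update(model, subject_cycles[seq_len(n_strides)],
                         max_epochs = max_epochs, rmse_stop = rmse_stop)
  model$provenance <- paste0(model$provenance, "+personalized")
  model
}

#' Sequential (cyclic) learning over a stride stream
#'
#' Prequential discipline: every stride is estimated and its RMSE/CC logged
#' *before* it is ever used for training; after every `interval` strides the
#' model is fine-tuned (warm start, capped epochs) on the cycles seen so far.
#' The number of update cycles is `floor(n / interval)`.
#'
#' @param model A trained `gru_am`.
#' @param stream_cycles Ordered list of normalized `gait_cycle`s.
#' @param interval Strides between updates (default 3).
#' @param update_epochs Epoch cap per fine-tune (default 50).
#' @param rmse_stop Early stop for each fine-tune, degrees.
#' @param buffer `"all"` (accumulate all strides seen, default) or
#'   `"window"` (sliding window of the last `k` strides).
#' @param k Sliding-window length when `buffer = "window"`.
#' @return A list of class `"sequential_log"`: `log` (per-stride data.frame
#'   with `stride`, `rmse`, `cc`, `cycle`), `n_updates`, `convergence_rate`,
#'   and the updated `model`.
#' @export
sequential_learn <- function(model, stream_cycles, interval = 3,
                             update_epochs = 50, rmse_stop = model$rmse_stop,
                             buffer = c("all", "window"), k = 10) {
  buffer <- match.arg(buffer)
  n <- length(stream_cycles)
  if (n < 1L) stop("empty stream")
  if (interval < 1L) stop("'interval' must be >= 1")
  log <- data.frame(stride = seq_len(n), rmse = NA_real_, cc = NA_real_,
                    cycle = NA_integer_)
  for (i in seq_len(n)) {
    cy <- stream_cycles[[i]]
    pred <- predict(model, cy)[1, ]
    log$rmse[i] <- rmse(cy$angle, pred)
    log$cc[i] <- cc(cy$angle, pred)
    log$cycle[i] <- i %/% interval
    if (i %% interval == 0L) {
      buf <- if (buffer == "all") stream_cycles[seq_len(i)]
             else stream_cycles[max(1L, i - k + 1L):i]
      model <- gru_am_update(model, buf, max_epochs = update_epochs,
                             rmse_stop = rmse_stop)
    }
  }
  structure(list(log = log, n_updates = as.integer(n %/% interval),
                 convergence_rate = if (n >= 2L) convergence_rate(log$rmse)
                                    else NA_real_,
                 model = model),
            class = "sequential_log")
}

#' @export
print.sequential_log <- function(x, ...) {
  cat(sprintf("sequential run: %d strides, %d update cycles\n",
              nrow(x$log), x$n_updates))
  cat(sprintf("  RMSE first %.2f -> last %.2f deg; convergence rate %+.3f deg/stride\n",
              x$log$rmse[1], x$log$rmse[nrow(x$log)], x$convergence_rate))
  invisible(x)
}

#' Progressive adaptation across visits
#'
#' Runs [sequential_learn()] over each visit's stride stream in order, with
#' the model state carried over between visits. Mirrors a multi-session
#' clinical workflow where the estimator keeps adapting to a participant.
#'
#' @param model A pretrained `gru_am`.
#' @param visits Ordered list of cycle streams (lists of `gait_cycle`s).
#' @param interval Strides between updates.
#' @param ... Passed to [sequential_learn()].
#' @return A list of class `"visit_log"`: `logs` (one `sequential_log` per
#'   visit), `summary` (per-visit mean RMSE/CC), and the final `model`.
#' @export
progressive_visits <- function(model, visits, interval = 3, ...) {
  if (length(visits) < 1L) stop("need at least one visit")
  logs <- vector("list", length(visits))
  for (v in seq_along(visits)) {
    run <- sequential_learn(model, visits[[v]], interval = interval, ...)
    model <- run$model
    run$model <- NULL
    logs[[v]] <- run
  }
  summ <- data.frame(
    visit = seq_along(visits),
    strides = vapply(logs, function(l) nrow(l$log), integer(1)),
    updates = vapply(logs, `[[`, integer(1), "n_updates"),
    rmse = vapply(logs, function(l) mean(l$log$rmse), numeric(1)),
    cc = vapply(logs, function(l) mean(l$log$cc), numeric(1)))
  structure(list(logs = logs, summary = summ, model = model),
            class = "visit_log")
}

#' @export
print.visit_log <- function(x, ...) {
  cat("progressive adaptation across", nrow(x$summary), "visit(s):\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  visit %d: %d strides, %d updates, mean RMSE %.2f deg, CC %.3f\n",
                x$summary$visit[i], x$summary$strides[i], x$summary$updates[i],
                x$summary$rmse[i], x$summary$cc[i]))
  invisible(x)
}
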