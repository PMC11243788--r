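test_that("compare_models reports both arms per seed, reproducibly", {
  ds <- gait_dataset(make_cycles(6), train_frac = 0.5)
  tab <- compare_models(ds, n_seeds = 1, hidden = 8, max_epochs = 3)
  expect_s3_class(tab, "model_comparison")
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$model, c("GRU-AM", "GRU"))
  tab2 <- compare_models(ds, n_seeds = 1, hidden = 8, max_epochs = 3)
  expect_identical(tab, tab2)
})

test_that("ablation reports one ranked entry per channel and finds the
           unique driver, sparing a duplicated channel", {
  # D uniquely drives the angle; A and B are exact duplicates of each other
  u <- (0:99) / 99
  shape_d <- exp(-0.5 * ((u - 0.4) / 0.15)^2)
  shape_a <- exp(-0.5 * ((u - 0.75) / 0.12)^2)
  set.seed(19)
  cycles <- lapply(1:24, function(i) {
    gd <- 1 + 0.25 * rnorm(1)
    ga <- 1 + 0.25 * rnorm(1)
    emg <- cbind(D = gd * shape_d, A = ga * shape_a, B = ga * shape_a)
    structure(list(start_s = i - 1, end_s = i, emg = emg,
                   emg_times = u + i - 1,
                   angle = 10 + 40 * emg[, "D"] + 15 * emg[, "A"],
                   angle_times = u + i - 1, channels = c("D", "A", "B"),
                   side = "right", normalized = TRUE, L = 100L),
              class = "gait_cycle")
  })
  ds <- gait_dataset(cycles, train_frac = 0.6)
  rep <- ablate_channels(ds, seed = 2, hidden = 12, max_epochs = 400,
                         rmse_stop = 1.5)
  expect_s3_class(rep, "ablation_report")
  expect_equal(nrow(rep$table), 3L)
  expect_setequal(rep$table$channel, c("D", "A", "B"))
  expect_setequal(rep$table$rank, 1:3)
  # the unique driver tops the ranking, and hurts more than the duplicate
  expect_equal(rep$table$channel[1], "D")
  dA <- rep$table$delta_rmse[rep$table$channel == "A"]
  dD <- rep$table$delta_rmse[rep$table$channel == "D"]
  expect_lt(dA, dD)
  expect_error(ablate_channels(gait_dataset(make_cycles(4, channels = "TA"),
                                            0.5)), "at least 2")
})

test_that("transfer pretraining validates the shared 6-channel set", {
  ds8 <- fix_ds  # 8-channel dataset
  expect_error(pretrain_transfer(ds8, hidden = 8, max_epochs = 1),
               "shared set")
  sh <- gait_dataset(make_cycles(6, channels = c("TA", "MG", "SL", "VL",
                                                 "RF", "MH")), 0.5)
  fit <- pretrain_transfer(sh, hidden = 8, max_epochs = 2)
  expect_equal(fit$provenance, "source-pretrain")
  # provenance lands in the checkpoint sidecar
  dir <- withr::local_tempdir()
  save_gru_am(fit, dir)
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"))
  expect_equal(side$provenance, "source-pretrain")
})

test_that("personalization is a no-op at 0 strides and errors when short", {
  sh <- gait_dataset(make_cycles(6, channels = c("TA", "MG", "SL", "VL",
                                                 "RF", "MH")), 0.5)
  fit <- pretrain_transfer(sh, hidden = 8, max_epochs = 2)
  expect_identical(personalize(fit, sh$cycles, n_strides = 0), fit)
  expect_error(personalize(fit, sh$cycles[1:3], n_strides = 10),
               "insufficient")
})

test_that("personalization lowers the subject's own test error", {
  ch6 <- c("TA", "MG", "SL", "VL", "RF", "MH")
  source_cycles <- make_cycles(10, channels = ch6, seed = 1)
  # subject with a different envelope-to-angle gain and offset
  subj <- make_cycles(16, channels = ch6, seed = 99,
                      angle_fun = function(emg) 18 + 42 * emg[, 1])
  src <- gait_dataset(source_cycles, train_frac = 0.6)
  fit <- pretrain_transfer(src, hidden = 12, max_epochs = 60, rmse_stop = 2,
                           seed = 5)
  held_out <- subj[11:16]
  err <- function(model) {
    pred <- predict(model, held_out)
    meas <- do.call(rbind, lapply(held_out, `[[`, "angle"))
    sqrt(mean((pred - meas)^2))
  }
  before <- err(fit)
  pers <- personalize(fit, subj, n_strides = 10, max_epochs = 120,
                      rmse_stop = 2)
  expect_equal(pers$provenance, "source-pretrain+personalized")
  expect_lt(err(pers), before)
})

test_that("sequential learning keeps the floor(n / interval) update count", {
  ds <- gait_dataset(make_cycles(6), train_frac = 0.5)
  fit <- quick_fit(ds, max_epochs = 2)
  stream30 <- make_cycles(30, seed = 7)
  run <- sequential_learn(fit, stream30, interval = 3, update_epochs = 0)
  expect_equal(run$n_updates, 10L)
  expect_equal(nrow(run$log), 30L)
  run15 <- sequential_learn(fit, stream30[1:15], interval = 3,
                            update_epochs = 0)
  expect_equal(run15$n_updates, 5L)
  # interval longer than the stream: no updates, full log
  run_big <- sequential_learn(fit, stream30[1:4], interval = 9,
                              update_epochs = 0)
  expect_equal(run_big$n_updates, 0L)
  expect_equal(nrow(run_big$log), 4L)
  expect_false(anyNA(run_big$log$rmse))
  # property: floor identity over assorted stream/interval combinations
  for (cfg in list(c(7, 2), c(9, 4), c(12, 5), c(5, 1))) {
    r <- sequential_learn(fit, stream30[seq_len(cfg[1])], interval = cfg[2],
                          update_epochs = 0)
    expect_equal(r$n_updates, cfg[1] %/% cfg[2])
  }
  expect_error(sequential_learn(fit, list(), interval = 3), "empty stream")
})

test_that("sequential learning is prequential: strides are scored before
           they are trained on", {
  ds <- gait_dataset(make_cycles(6), train_frac = 0.5)
  fit <- quick_fit(ds, max_epochs = 2)
  stream <- make_cycles(6, seed = 31)
  run <- sequential_learn(fit, stream, interval = 2, update_epochs = 5)
  # the first logged RMSE must equal the untouched model's estimate
  manual <- rmse(stream[[1]]$angle, predict(fit, stream[[1]])[1, ])
  expect_equal(run$log$rmse[1], manual)
  # and the model did change over the run
  expect_false(identical(run$model$params, fit$params))
})

test_that("progressive visits carry state and reduce to sequential_learn", {
  ds <- gait_dataset(make_cycles(6), train_frac = 0.5)
  fit <- quick_fit(ds, max_epochs = 2)
  visits <- list(make_cycles(15, seed = 41), make_cycles(30, seed = 42),
                 make_cycles(30, seed = 43))
  runs <- progressive_visits(fit, visits, interval = 3, update_epochs = 0)
  expect_equal(runs$summary$updates, c(5L, 10L, 10L))
  expect_equal(runs$summary$strides, c(15L, 30L, 30L))
  single <- progressive_visits(fit, visits[1], interval = 3,
                               update_epochs = 0)
  direct <- sequential_learn(fit, visits[[1]], interval = 3,
                             update_epochs = 0)
  expect_equal(single$logs[[1]]$log, direct$log)
})

test_that("a healthy-pretrained model adapts within CP visits", {
  sh <- synthesize_trial(gait_presets("shared6"), n_strides = 10, seed = 51)
  src <- prepare_dataset(sh)
  fit <- pretrain_transfer(src, hidden = 16, max_epochs = 80, rmse_stop = 4,
                           seed = 2)
  cp_cycles <- function(visit, n, seed) {
    trial <- synthesize_trial(gait_presets("cp6", visit = visit), n,
                              seed = seed)
    ds <- prepare_dataset(trial, train_frac = 0.9)
    ds$cycles
  }
  visits <- list(cp_cycles(1, 6, 61), cp_cycles(2, 9, 62))
  runs <- progressive_visits(fit, visits, interval = 3, update_epochs = 25)
  for (l in runs$logs) {
    n <- nrow(l$log)
    expect_lte(l$log$rmse[n], l$log$rmse[1])
  }
})
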