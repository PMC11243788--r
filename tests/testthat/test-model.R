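test_that("alignment score follows Va' tanh(Ua s + Wa h)", {
  H <- 4
  p0 <- list(Va = rep(0, H), Ua = diag(H), Wa = diag(H))
  expect_equal(alignment_score(p0, rnorm(H), rnorm(H)), 0)
  pz <- list(Va = rnorm(H), Ua = matrix(0, H, H), Wa = matrix(0, H, H))
  expect_equal(alignment_score(pz, rnorm(H), rnorm(H)), 0)
  # scalar case: Va = 1, Ua = 0, Wa = 1, h = 0.5 -> tanh(0.5)
  ps <- list(Va = 1, Ua = matrix(0, 1, 1), Wa = matrix(1, 1, 1))
  expect_equal(alignment_score(ps, 0.3, 0.5), tanh(0.5), tolerance = 1e-12)
  expect_equal(tanh(0.5), 0.46212, tolerance = 1e-5)
  expect_error(alignment_score(ps, c(1, 2), 0.5), "dimension mismatch")
})

test_that("attention weights are a softmax over scores", {
  expect_equal(attention_weights(rep(1.7, 4)), rep(0.25, 4))
  expect_equal(attention_weights(c(0, log(2))), c(1 / 3, 2 / 3))
  expect_equal(attention_weights(5), 1)
  expect_error(attention_weights(c(0, NaN)), "non-finite")
  # property: positive, sum to 1, over random shapes
  set.seed(8)
  for (k in 1:20) {
    w <- attention_weights(rnorm(sample(1:50, 1), sd = 5))
    expect_true(all(w > 0))
    expect_equal(sum(w), 1)
  }
})

test_that("context vector is the weighted sum of encoder states", {
  h1 <- rnorm(5)
  expect_equal(context_vector(1, matrix(h1, 1)), h1)
  H <- matrix(rep(h1, 3), 3, byrow = TRUE)
  expect_equal(context_vector(c(0.2, 0.5, 0.3), H), h1)
  expect_equal(context_vector(c(0.25, 0.75), matrix(c(1, 3), 2)), 2.5)
  expect_error(context_vector(c(0.5, 0.5), matrix(1, 3, 2)), "match")
})

test_that("context is permutation-invariant and stays in the convex hull", {
  set.seed(15)
  for (k in 1:20) {
    M <- sample(2:30, 1); Hn <- sample(1:10, 1)
    st <- matrix(rnorm(M * Hn), M)
    w <- attention_weights(rnorm(M))
    ctx <- context_vector(w, st)
    perm <- sample(M)
    expect_equal(context_vector(w[perm], st[perm, , drop = FALSE]), ctx)
    expect_true(all(ctx >= apply(st, 2, min) - 1e-12))
    expect_true(all(ctx <= apply(st, 2, max) + 1e-12))
  }
})

test_that("zero weights pin the decoder at its fixed point: constant output", {
  ds <- gait_dataset(make_cycles(4), train_frac = 0.5)
  fit <- gru_am(ds, hidden = 6, max_epochs = 0, seed = 1)
  fit$params <- lapply(fit$params, function(p) p * 0)
  pred <- predict(fit, ds, which = "test")
  # sigma(0) = 0.5 on the normalized scale at every step
  mid <- fit$stats$angle_min + 0.5 * (fit$stats$angle_max - fit$stats$angle_min)
  expect_equal(unname(pred), matrix(mid, nrow(pred), 100))
})

test_that("estimates have length L and live inside the training angle range", {
  fit <- quick_fit(fix_ds)
  pred <- predict(fit, fix_ds, which = "test")
  expect_equal(ncol(pred), 100L)
  expect_true(all(pred >= fit$stats$angle_min))
  expect_true(all(pred <= fit$stats$angle_max))
})

test_that("training is seeded and fully reproducible", {
  ds <- gait_dataset(make_cycles(6), train_frac = 0.5)
  f1 <- gru_am(ds, hidden = 8, max_epochs = 4, seed = 42)
  f2 <- gru_am(ds, hidden = 8, max_epochs = 4, seed = 42)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, ds), predict(f2, ds))
})

test_that("a zero epoch budget returns the initialized model untouched", {
  ds <- gait_dataset(make_cycles(4), train_frac = 0.5)
  fit <- gru_am(ds, hidden = 8, max_epochs = 0, seed = 7)
  expect_equal(nrow(fit$history), 0L)
  expect_equal(fit$terminated, "max_epochs")
})

test_that("the baseline lacks exactly the attention parameters", {
  ds <- gait_dataset(make_cycles(4), train_frac = 0.5)
  H <- 12
  am <- gru_am(ds, hidden = H, max_epochs = 0, seed = 1)
  base <- gru_am(ds, hidden = H, max_epochs = 0, seed = 1, attention = FALSE)
  n_am <- sum(vapply(am$params, length, integer(1)))
  n_base <- sum(vapply(base$params, length, integer(1)))
  expect_equal(n_am - n_base, 2 * H^2 + H)
})

test_that("with one encoder state GRU and GRU-AM decode identically", {
  # L = window = 20 with a single channel -> M = 1 segment
  cycles <- make_cycles(4, channels = "TA", L = 20)
  ds <- gait_dataset(cycles, train_frac = 0.5, L = 20)
  am <- gru_am(ds, hidden = 9, window = 20, max_epochs = 0, seed = 3)
  base <- gru_am(ds, hidden = 9, window = 20, max_epochs = 0, seed = 3,
                 attention = FALSE)
  # shared (non-attention) parameters are drawn identically under one seed
  expect_identical(am$params[names(base$params)], base$params)
  expect_equal(predict(am, ds, which = "test"),
               predict(base, ds, which = "test"))
})

test_that("checkpoints restore the estimator bit-exactly", {
  fit <- quick_fit(fix_ds, max_epochs = 2)
  before <- predict(fit, fix_ds, which = "test")
  dir <- withr::local_tempdir()
  save_gru_am(fit, dir)
  back <- load_gru_am(dir)
  expect_identical(back$params, fit$params)
  expect_identical(predict(back, fix_ds, which = "test"), before)
})

test_that("estimating from a segment sequence matches the cycle path", {
  fit <- quick_fit(fix_ds, max_epochs = 2)
  cy <- fix_ds$cycles[[8]]
  expect_equal(predict(fit, segment_cycle(cy, 20)), predict(fit, cy))
})

test_that("channel mismatches are reported by name", {
  fit <- quick_fit(fix_ds, max_epochs = 1)
  cy <- make_cycles(1, channels = c("TA", "RF"))[[1]]
  expect_error(predict(fit, cy), "missing \\[.*MG")
})

test_that("a noise-free envelope-driven angle is learned to low error", {
  cycles <- make_cycles(12, channels = "TA", seed = 13, gain_sd = 0.05)
  ds <- gait_dataset(cycles, train_frac = 0.6)
  fit <- gru_am(ds, hidden = 16, rmse_stop = 1, max_epochs = 600, seed = 1)
  expect_equal(fit$terminated, "rmse")
  pred <- predict(fit, ds, which = "test")
  meas <- do.call(rbind, lapply(ds$cycles[ds$split == "test"], `[[`, "angle"))
  expect_lt(sqrt(mean((pred - meas)^2)), 5)
})

test_that("training history records both termination criteria", {
  ds <- gait_dataset(make_cycles(6), train_frac = 0.5)
  capped <- gru_am(ds, hidden = 8, max_epochs = 3, seed = 1)
  expect_equal(capped$terminated, "max_epochs")
  expect_equal(nrow(capped$history), 3L)
  expect_named(capped$history, c("epoch", "loss", "rmse"))
})
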