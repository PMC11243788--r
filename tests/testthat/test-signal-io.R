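test_that("recording and series constructors enforce their invariants", {
  expect_error(emg_recording(matrix(1:4, 2), 0, c("a", "b")), "positive")
  expect_error(emg_recording(matrix(1:4, 2), 100, c("a", "a")), "unique")
  expect_error(angle_series(c(1, NA), 100), "finite")
  expect_error(event_list(c(1, 1), "right"), "strictly increasing")
  r <- emg_recording(matrix(rnorm(20), 10), 1000, c("TA", "MG"))
  expect_s3_class(r, "emg_recording")
  expect_equal(r$channels, c("TA", "MG"))
})

test_that("a plain 3-column CSV reads as a 2-channel recording at 1000 Hz", {
  path <- withr::local_tempfile(fileext = ".csv")
  tm <- (0:999) / 1000
  writeLines(c("time_s,TA,MG",
               sprintf("%.6f,%.6f,%.6f", tm, sin(tm), cos(tm))), path)
  r <- read_timeseries(path)
  expect_s3_class(r, "emg_recording")
  expect_equal(r$rate_hz, 1000, tolerance = 1e-9)
  expect_equal(r$channels, c("TA", "MG"))
  expect_equal(nrow(r$samples), 1000)
})

test_that("write/read round trip preserves values over random shapes", {
  set.seed(7)
  for (k in 1:5) {
    n <- sample(2:200, 1)
    C <- sample(1:6, 1)
    rate <- sample(c(100, 1000, 2000), 1)
    r <- emg_recording(matrix(rnorm(n * C), n), rate, paste0("ch", seq_len(C)))
    path <- withr::local_tempfile(fileext = ".csv")
    write_timeseries(r, path)
    r2 <- read_timeseries(path)
    expect_lt(max(abs(r2$samples - r$samples)), 1e-9)
    expect_equal(r2$rate_hz, rate, tolerance = 1e-6)
    expect_equal(r2$channels, r$channels)
  }
})

test_that("a 1-sample recording writes a 2-line file", {
  r <- emg_recording(matrix(1.5), 100, "TA")
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(r, path)
  expect_length(readLines(path), 2L)
})

test_that("rate declaration is validated within 1%", {
  path <- withr::local_tempfile(fileext = ".csv")
  tm <- (0:99) * 0.01
  writeLines(c("time_s,angle", sprintf("%.6f,%.3f", tm, sin(tm))), path)
  a <- read_timeseries(path, expected_rate = 100)
  expect_s3_class(a, "angle_series")
  expect_equal(a$rate_hz, 100)
  expect_error(read_timeseries(path, expected_rate = 120), "rate error")
})

test_that("format errors are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("not_time,TA", "0,1"), path)
  expect_error(read_timeseries(path), "format error")
  writeLines(c("time_s,TA", "0.00,1", "0.02,2", "0.01,3"), path)
  expect_error(read_timeseries(path), "non-monotone")
})

test_that("inferred rate of a constant-step series is the step reciprocal", {
  path <- withr::local_tempfile(fileext = ".csv")
  r <- emg_recording(matrix(rnorm(500)), 2000, "VL")
  write_timeseries(r, path)
  expect_equal(read_timeseries(path)$rate_hz, 2000, tolerance = 1e-9)
})

test_that("align_streams trims to the common window and is idempotent", {
  emg <- emg_recording(matrix(rnorm(10000 * 2), ncol = 2), 1000,
                       c("TA", "MG"), t0 = 0)
  ang <- angle_series(rnorm(800), 100, t0 = 1)  # spans [1, 9]
  al <- align_streams(emg, ang)
  expect_equal(al$start_s, 1)
  expect_equal(al$end_s, 8.99, tolerance = 1e-6)
  al2 <- align_streams(al$emg, al$angle)
  expect_equal(al2$emg$samples, al$emg$samples)
  expect_equal(al2$angle$values, al$angle$values)
  # identical supports -> unchanged
  emg_b <- emg_recording(matrix(rnorm(991)), 1000, "TA", t0 = 0)
  ang_b <- angle_series(rnorm(100), 100, t0 = 0)
  al4 <- align_streams(emg_b, ang_b)
  expect_equal(nrow(al4$emg$samples), 991)
  expect_length(al4$angle$values, 100)
})

test_that("2000 Hz EMG against 100 Hz angle keeps a 20:1 sample ratio", {
  emg <- emg_recording(matrix(rnorm(20000)), 2000, "TA", t0 = 0)
  ang <- angle_series(rnorm(900), 100, t0 = 0.5)
  al <- align_streams(emg, ang)
  ratio <- nrow(al$emg$samples) / length(al$angle$values)
  expect_lt(abs(ratio - 20), 0.05)
})

test_that("non-overlapping streams raise an alignment error", {
  emg <- emg_recording(matrix(rnorm(100)), 1000, "TA", t0 = 0)
  ang <- angle_series(rnorm(100), 100, t0 = 50)
  expect_error(align_streams(emg, ang), "alignment error")
})

test_that("event and manifest files round-trip and validate", {
  ev <- event_list(c(0, 1.1, 2.2), "right")
  epath <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, epath)
  expect_equal(read_events(epath), ev)

  dir <- withr::local_tempdir()
  r <- emg_recording(matrix(rnorm(200), ncol = 2), 1000, c("TA", "MG"))
  write_timeseries(r, file.path(dir, "emg.csv"))
  write_timeseries(angle_series(rnorm(10), 100), file.path(dir, "angle.csv"))
  write_events(ev, file.path(dir, "events.csv"))
  m <- list(emg = "emg.csv", angle = "angle.csv", events = "events.csv",
            channels = c("TA", "MG"), rate_emg = 1000, rate_angle = 100)
  write_manifest(m, file.path(dir, "manifest.yaml"))
  m2 <- read_manifest(file.path(dir, "manifest.yaml"))
  expect_equal(m2$channels, c("TA", "MG"))
  m$channels <- c("TA", "XX")
  write_manifest(m, file.path(dir, "bad.yaml"))
  expect_error(read_manifest(file.path(dir, "bad.yaml")), "channels")
  m$channels <- c("TA", "MG"); m$emg <- "nope.csv"
  write_manifest(m, file.path(dir, "bad2.yaml"))
  expect_error(read_manifest(file.path(dir, "bad2.yaml")), "missing file")
})
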