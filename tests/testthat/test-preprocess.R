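test_that("beat_series reconstructs times from rr and validates input", {
  b <- beat_series(rr_ms = c(400, 400, 500))
  expect_equal(b$time_s, c(0.4, 0.8, 1.3))
  expect_error(beat_series(rr_ms = c(400, -1)), "positive")
  expect_error(beat_series(time_s = c(1, 1), rr_ms = c(400, 400)), "increasing")
  expect_error(beat_series(rr_ms = numeric(0)), "at least one")
})

test_that("single doubled beat is flagged, clean series is untouched", {
  b <- constant_beats(300)
  b$rr_ms[137] <- 800
  f <- flag_artifacts(b)
  expect_identical(which(f$flag != "valid"), 137L)
  expect_identical(f$flag[137], "missed")
  clean <- flag_artifacts(constant_beats(300))
  expect_true(all(clean$flag == "valid"))
})

test_that("flagging matches the brute-force running-median oracle", {
  set.seed(42)
  rr <- 400 + cumsum(rnorm(300, 0, 2))
  bad_at <- c(20, 77, 150, 222, 290)
  rr[bad_at] <- rr[bad_at] * 2
  b <- beat_series(rr_ms = rr)
  f <- flag_artifacts(b)
  expect_identical(which(f$flag != "valid"), as.integer(bad_at))
  # oracle agreement on the first pass decision set
  expect_identical(which(oracle_flag(rr, rep(TRUE, 300))), as.integer(bad_at))
})

test_that("flagging is idempotent and preserves beat count", {
  set.seed(7)
  rr <- 400 + rnorm(200, 0, 8)
  hit <- sample(200, 6)
  rr[hit] <- rr[hit] * 1.8
  b <- flag_artifacts(beat_series(rr_ms = pmax(rr, 150)))
  expect_identical(flag_artifacts(b)$flag, b$flag)
  expect_identical(nrow(b), 200L)
  cleaned <- suppressWarnings(replace_artifacts(b)) # outlier may sit at an edge
  expect_identical(nrow(cleaned), 200L)
  # flag -> replace -> flag produces no new flags
  expect_identical(flag_artifacts(cleaned)$flag, cleaned$flag)
})

test_that("fewer than 12 beats skips flagging with a warning", {
  b <- constant_beats(10)
  expect_warning(f <- flag_artifacts(b), "fewer than 12")
  expect_identical(f$flag, b$flag)
})

test_that("replacement interpolates linearly between valid neighbours", {
  b <- beat_series(rr_ms = c(400, 400, 800, 400, 400),
                   flag = c("valid", "valid", "missed", "valid", "valid"))
  r <- replace_artifacts(b)
  expect_equal(r$rr_ms[3], 400)
  expect_identical(r$flag[3], "interpolated")
  b2 <- beat_series(rr_ms = c(400, 999, 500),
                    flag = c("valid", "ectopic", "valid"))
  expect_equal(replace_artifacts(b2)$rr_ms[2], 450)
})

test_that("scattered flagged beats match the piecewise-linear oracle", {
  set.seed(11)
  rr <- seq(350, 450, length.out = 120) # ramp
  bad <- sort(sample(2:119, 10))
  flag <- rep("valid", 120); flag[bad] <- "ectopic"
  b <- beat_series(rr_ms = rr, flag = flag)
  r <- replace_artifacts(b)
  expect_equal(r$rr_ms, oracle_interp(rr, flag != "valid"), tolerance = 1e-12)
  # valid beats bit-identical
  expect_identical(r$rr_ms[flag == "valid"], rr[flag == "valid"])
})

test_that("edge runs are held at the nearest valid value with a warning", {
  b <- beat_series(rr_ms = c(900, 400, 410, 420),
                   flag = c("missed", "valid", "valid", "valid"))
  expect_warning(r <- replace_artifacts(b), "edge")
  expect_equal(r$rr_ms[1], 400)
})

test_that("resampling reproduces constants and affine ramps exactly", {
  u <- resample_uniform(beat_series(rr_ms = rep(500, 200)))
  expect_true(all(u$values == 500))
  expect_equal(u$rate, 8)
  # two beats at t=0+ and a 10 ms/sample ramp
  b <- beat_series(time_s = c(0, 1), rr_ms = c(400, 480))
  u2 <- resample_uniform(b)
  expect_equal(u2$values, seq(400, 480, by = 10))
  # affine signals are reproduced exactly on a long irregular grid
  set.seed(3)
  t <- cumsum(runif(500, 0.3, 0.5))
  rr <- 300 + 2 * t
  u3 <- resample_uniform(beat_series(time_s = t, rr_ms = rr))
  grid <- t[1] + (seq_along(u3$values) - 1) / 8
  expect_equal(u3$values, 300 + 2 * grid, tolerance = 1e-12)
})

test_that("resampling matches the closed-form interpolant on modulated beats", {
  set.seed(9)
  t <- cumsum(runif(400, 0.35, 0.45))
  rr <- 400 + 15 * sin(2 * pi * 0.1 * t)
  b <- beat_series(time_s = t, rr_ms = rr)
  u <- resample_uniform(b)
  n <- length(u$values)
  expect_identical(n, as.integer(floor((t[400] - t[1]) * 8) + 1))
  grid <- t[1] + (seq_len(n) - 1) / 8
  expect_equal(u$values, oracle_lininterp(t, rr, grid), tolerance = 1e-12)
  # linear interpolation cannot overshoot
  expect_true(all(u$values >= min(rr) & u$values <= max(rr)))
})

test_that("records shorter than 1 s cannot be resampled", {
  expect_error(resample_uniform(beat_series(rr_ms = c(400, 400))), "1 s")
})

test_that("rr files round-trip losslessly in both dialects", {
  dir <- withr::local_tempdir()
  set.seed(5)
  b <- beat_series(rr_ms = 400 + rnorm(50), flag = sample(beat_flags(), 50, TRUE))
  p <- file.path(dir, "rr.csv")
  write_rr(b, p)
  b2 <- read_rr(p)
  expect_equal(b2$time_s, b$time_s, tolerance = 1e-10)
  expect_equal(b2$rr_ms, b$rr_ms, tolerance = 1e-10)
  expect_identical(b2$flag, b$flag)
  # bare single column
  writeLines(sprintf("%.6f", b$rr_ms), p)
  b3 <- read_rr(p)
  expect_equal(b3$rr_ms, b$rr_ms, tolerance = 1e-6)
  expect_equal(b3$time_s, cumsum(b$rr_ms) / 1000, tolerance = 1e-6)
})

test_that("malformed rr files are rejected with the offending row", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.csv")
  writeLines(c("time_s,rr_ms", "0.4,400", "0.8,-10"), p)
  expect_error(read_rr(p), "row 2")
})
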