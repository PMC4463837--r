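test_that("high-pass filter removes gravity/DC and passes body movement", {
  fs <- 32
  # constant 1000 mG on all axes: DC must vanish after the transient
  s <- raw_accel_stream(x = rep(1000, 60 * fs), y = rep(1000, 60 * fs),
                        z = rep(1000, 60 * fs), sample_rate = fs)
  f <- highpass_filter(s)
  mid <- (10 * fs):(50 * fs)
  expect_lt(max(abs(f$x[mid])), 1)
  expect_lt(max(abs(f$z[mid])), 1)

  # 5 Hz sinusoid: steady-state amplitude must match the designed filter's
  # frequency response (forward-backward => squared magnitude), evaluated
  # independently from the transfer-function polynomials
  h_gain <- function(bf, f_hz, fs_hz) {
    z <- exp(-1i * 2 * pi * f_hz / fs_hz * (seq_along(bf$b) - 1))
    za <- exp(-1i * 2 * pi * f_hz / fs_hz * (seq_along(bf$a) - 1))
    Mod(sum(bf$b * z) / sum(bf$a * za))
  }
  tt <- (0:(60 * fs - 1)) / fs
  sig <- 100 * sin(2 * pi * 5 * tt)
  bf <- signal::butter(4, 0.7 / (fs / 2), type = "high")
  gain <- h_gain(bf, 5, fs)^2
  s5 <- raw_accel_stream(x = sig, y = sig, z = sig, sample_rate = fs)
  f5 <- highpass_filter(s5)
  amp <- max(abs(f5$x[mid]))
  expect_equal(amp, 100 * gain, tolerance = 0.02)
  expect_equal(amp, 100, tolerance = 0.02)  # 5 Hz is deep in the passband

  # superposition: offset + 2 Hz sinusoid -> the sinusoid alone
  sig2 <- 50 * sin(2 * pi * 2 * tt)
  g2 <- h_gain(bf, 2, fs)^2
  sC <- raw_accel_stream(x = 1000 + sig2, y = rep(0, length(tt)),
                         z = rep(0, length(tt)), sample_rate = fs)
  fC <- highpass_filter(sC)
  resid <- fC$x[mid] - g2 * sig2[mid]
  expect_lt(sqrt(mean(resid^2)), 2)
})

test_that("high-pass filter validates cutoff and stream length", {
  s <- raw_accel_stream(x = rep(0, 10), y = rep(0, 10), z = rep(0, 10))
  expect_error(highpass_filter(s), "too short")
  expect_error(highpass_filter(s, cutoff = 20), "cutoff")
  long <- raw_accel_stream(x = rnorm(200), y = rnorm(200), z = rnorm(200))
  expect_silent(highpass_filter(long))
})

test_that("filtering an already-filtered band-limited signal is near-idempotent", {
  fs <- 32
  set.seed(71)
  tt <- (0:(120 * fs - 1)) / fs
  sig <- 40 * sin(2 * pi * 3 * tt) + 20 * sin(2 * pi * 6.5 * tt + 1)
  s <- raw_accel_stream(x = sig, y = sig, z = sig, sample_rate = fs)
  f1 <- highpass_filter(s)
  f2 <- highpass_filter(f1)
  mid <- (20 * fs):(100 * fs)
  rms1 <- sqrt(mean(f1$x[mid]^2)); rms2 <- sqrt(mean(f2$x[mid]^2))
  expect_lt(abs(rms2 - rms1) / rms1, 0.01)
})

test_that("synthetic acceleration is the per-sample Euclidean norm", {
  s <- raw_accel_stream(x = c(3, 0), y = c(4, 0), z = c(0, 0), sample_rate = 1)
  expect_equal(synthetic_acceleration(s), c(5, 0))

  set.seed(11)
  x <- runif(1000, -500, 500); y <- runif(1000, -500, 500)
  z <- runif(1000, -500, 500)
  s <- raw_accel_stream(x, y, z, sample_rate = 32)
  oracle <- vapply(seq_len(1000),
                   function(i) sqrt(x[i]^2 + y[i]^2 + z[i]^2), numeric(1))
  expect_equal(synthetic_acceleration(s), oracle)

  # invariance under axis permutation and sign flips
  expect_equal(synthetic_acceleration(raw_accel_stream(z, -x, y, sample_rate = 32)),
               oracle)
})

test_that("minute aggregation averages full epochs and drops the remainder", {
  fs <- 32
  expect_equal(aggregate_to_minutes(rep(10, 120 * fs), fs)$value, c(10, 10))
  expect_equal(aggregate_to_minutes(c(rep(0, 60 * fs), rep(20, 60 * fs)), fs)$value,
               c(0, 20))
  # ramp 0..N-1 over one epoch -> mean (N-1)/2
  n <- 60 * fs
  expect_equal(aggregate_to_minutes(0:(n - 1), fs)$value, (n - 1) / 2)
  # trailing partial epoch dropped
  expect_equal(nrow(aggregate_to_minutes(rep(1, 90 * fs), fs)), 1L)
  expect_error(aggregate_to_minutes(numeric(0)), "empty")
  expect_error(aggregate_to_minutes(rep(1, 10), 32), "shorter")
})

test_that("infrared minute percent ORs sensors then counts positive seconds", {
  mk <- function(flagsA, flagsB) {
    data.frame(time_s = rep(seq_along(flagsA) - 1L, 2),
               sensor_id = rep(c("A", "B"), each = length(flagsA)),
               hit = c(flagsA, flagsB))
  }
  expect_equal(infrared_minute_percent(mk(rep(1, 60), rep(0, 60)))$value, 100)
  expect_equal(infrared_minute_percent(mk(c(rep(1, 30), rep(0, 30)),
                                          rep(0, 60)))$value, 50)

  set.seed(5)
  a <- rbinom(300, 1, 0.3); b <- rbinom(300, 1, 0.2)
  got <- infrared_minute_percent(mk(a, b))
  oracle <- vapply(0:4, function(m) {
    sec <- (m * 60 + 1):(m * 60 + 60)
    100 * sum(a[sec] | b[sec]) / 60
  }, numeric(1))
  expect_equal(got$value, oracle)
  expect_identical(index_kind(got), "infrared")

  # a missing second is an error, never imputed
  df <- mk(a, b)
  expect_error(infrared_minute_percent(df[df$time_s != 42, ]), "missing seconds")
})

test_that("minute collapses are monotone in their inputs", {
  set.seed(8)
  lo <- runif(60 * 32, 0, 10)
  hi <- lo + runif(60 * 32, 0, 5)
  expect_true(all(aggregate_to_minutes(hi, 32)$value >=
                  aggregate_to_minutes(lo, 32)$value))
  flags_lo <- rbinom(120, 1, 0.3)
  flags_hi <- pmax(flags_lo, rbinom(120, 1, 0.3))
  mk1 <- function(f) data.frame(time_s = seq_along(f) - 1L, sensor_id = "A", hit = f)
  expect_true(all(infrared_minute_percent(mk1(flags_hi))$value >=
                  infrared_minute_percent(mk1(flags_lo))$value))
})

test_that("bout steady means use [start + 2, end - 1) and ignore edge spikes", {
  minute <- 0:29
  pa_v <- rep(15, 30)
  b <- bout_window("calib", 0, 20)
  ee <- energy_series(minute, rep(1.2, 30))
  pa <- activity_index(minute, pa_v, "accel")
  got <- bout_steady_means(ee, pa, list(b))
  expect_equal(got$ee_kcal_min, 1.2)
  expect_equal(got$pa_index, 15)
  expect_equal(got$n_minutes, 17L)  # minutes 2..18 inclusive

  # spikes confined to minutes 0, 1 and 19 leave the means untouched
  ee_sp <- rep(1.2, 30); ee_sp[c(1, 2, 20)] <- 9  # 0-based minutes 0, 1, 19
  got_sp <- bout_steady_means(energy_series(minute, ee_sp), pa, list(b))
  expect_equal(got_sp$ee_kcal_min, 1.2)

  # four bouts with known per-minute values match hand-computed means
  n <- 120
  set.seed(3)
  ee_v <- runif(n, 0.8, 2); pa_v <- runif(n, 0, 30)
  bouts <- lapply(c(0, 30, 60, 90), function(s) bout_window(paste0("b", s), s, s + 20))
  got <- bout_steady_means(energy_series(0:(n - 1), ee_v),
                           activity_index(0:(n - 1), pa_v, "accel"), bouts)
  for (i in seq_along(bouts)) {
    idx <- (bouts[[i]]$start + 2):(bouts[[i]]$end - 2) + 1L
    expect_equal(got$ee_kcal_min[i], mean(ee_v[idx]))
    expect_equal(got$pa_index[i], mean(pa_v[idx]))
  }

  # uncovered steady window names the bout
  short_ee <- energy_series(0:10, rep(1, 11))
  expect_error(bout_steady_means(short_ee, pa, list(bout_window("late", 5, 25))),
               "late")
})

test_that("raw 32 Hz rendering survives the full signal chain", {
  # pad with guard minutes: the zero-phase filter's edge transient and the
  # amplitude steps bleed ~1 s across minute boundaries
  targets <- c(5, 2, 6, 10, 20, 5, 5)
  raw <- render_raw_accel(targets)
  mag <- synthetic_acceleration(highpass_filter(raw))
  mins <- aggregate_to_minutes(mag, 32)
  inner <- 2:(length(targets) - 1)
  expect_equal(mins$value[inner], targets[inner], tolerance = 0.05)
})

test_that("constructors enforce their invariants", {
  expect_error(raw_accel_stream(1:3, 1:2, 1:3), "same length")
  expect_error(raw_accel_stream(7000, 0, 0), "sensor range")
  expect_error(activity_index(c(0, 0), c(1, 1), "accel"), "strictly increasing")
  expect_error(activity_index(0, 150, "infrared"), "\\[0, 100\\]")
  expect_error(activity_index(0, -1, "accel"), "non-negative")
  expect_error(bout_window("x", 0, 3), "too short")
  b <- bout_window("x", 10, 30)
  expect_equal(c(b$steady_start, b$steady_end), c(12, 29))
})
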