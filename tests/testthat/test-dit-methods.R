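test_that("fasting calibration recovers an exact line and matches closed-form OLS", {
  bm <- data.frame(ee_kcal_min = c(1.0, 1.2, 1.4, 1.6),
                   pa_index = c(0, 10, 20, 30))
  m <- fit_fasting_calibration(bm, "accel")
  expect_equal(m$slope, 0.02)
  expect_equal(m$intercept, 1.0)
  expect_equal(m$r, 1)
  expect_equal(m$n_points, 4L)

  set.seed(14)
  for (i in 1:5) {
    bm <- data.frame(ee_kcal_min = runif(4, 0.8, 2), pa_index = runif(4, 0, 30))
    m <- fit_fasting_calibration(bm, "accel")
    o <- ols_closed_form(bm$pa_index, bm$ee_kcal_min)
    expect_equal(m$slope, o$slope, tolerance = 1e-12)
    expect_equal(m$intercept, o$intercept, tolerance = 1e-12)
  }

  expect_error(fit_fasting_calibration(
    data.frame(ee_kcal_min = 1, pa_index = 5), "accel"), "at least 2")
  expect_error(fit_fasting_calibration(
    data.frame(ee_kcal_min = c(1, 2), pa_index = c(5, 5)), "accel"),
    "identical")
})

test_that("calibration slope is recovered from noisy simulated bouts", {
  set.seed(31)
  true_slope <- 0.02; true_int <- 0.9
  pa <- c(2, 6, 10, 20)
  slopes <- ses <- numeric(50)
  for (i in 1:50) {
    ee <- true_int + true_slope * pa + rnorm(4, 0, 0.01)
    m <- fit_fasting_calibration(data.frame(ee_kcal_min = ee, pa_index = pa),
                                 "accel")
    slopes[i] <- m$slope
    ses[i] <- 0.01 / sqrt(sum((pa - mean(pa))^2))  # analytic SE of the slope
  }
  expect_true(mean(abs(slopes - true_slope) < 3 * ses) > 0.9)
})

test_that("EEe prediction is the elementwise affine map and checks kinds", {
  m <- structure(list(slope = 0.02, intercept = 1.0, r = 1, n_points = 4,
                      pa_kind = "accel"), class = "calibration_model")
  pa0 <- activity_index(0:9, rep(0, 10), "accel")
  expect_equal(estimate_ee(m, pa0)$ee, rep(1.0, 10))
  pa25 <- activity_index(0, 25, "accel")
  expect_equal(estimate_ee(m, pa25)$ee, 1.5)

  set.seed(2)
  v <- c(runif(20, 0, 30), rep(0, 5), runif(20, 30, 60))
  pa <- activity_index(seq_along(v) - 1L, v, "accel")
  expect_equal(estimate_ee(m, pa)$ee, 1.0 + 0.02 * v)

  ir <- activity_index(0, 50, "infrared")
  expect_error(estimate_ee(m, ir), "does not match")
})

test_that("fasting-calibration DIT integrates EE - EEe over the windows", {
  minute <- 0:599
  eee <- structure(data.frame(minute = minute, ee = rep(1.1, 600)),
                   class = c("energy_series", "data.frame"))
  w <- postprandial_windows(100, 460)  # 360 min
  # EE identical to EEe -> zero (the fasted theoretical value)
  ee_same <- energy_series(minute, rep(1.1, 600))
  expect_equal(nihn_dit(ee_same, eee, w)$total_kcal, 0)
  # constant +0.1 kcal/min offset -> 36 kcal
  ee_off <- energy_series(minute, rep(1.2, 600))
  r <- nihn_dit(ee_off, eee, w, intake = 720)
  expect_equal(r$total_kcal, 36)
  expect_equal(r$percent_of_intake, 5)
  expect_equal(sum(r$time_course$dit_kcal_min), r$total_kcal)

  # additivity over disjoint windows
  set.seed(77)
  ee_r <- energy_series(minute, runif(600, 0.8, 2.5))
  w1 <- postprandial_windows(100, 250)
  w2 <- postprandial_windows(300, 460)
  w12 <- postprandial_windows(c(100, 300), c(250, 460))
  expect_equal(nihn_dit(ee_r, eee, w12)$total_kcal,
               nihn_dit(ee_r, eee, w1)$total_kcal +
                 nihn_dit(ee_r, eee, w2)$total_kcal)

  short <- energy_series(0:99, rep(1, 100))
  expect_error(nihn_dit(short, eee, w), "not fully covered")
})

test_that("intercept-method DIT matches a constructed linear oracle", {
  n <- 480
  minute <- 0:(n - 1)
  pa_v <- 5 + 10 * ((minute %/% 30) %% 3)  # three distinct bin levels
  bmr <- 0.9 * 1440
  w <- postprandial_windows(0, n)
  # EE exactly bmr_rate + 0.02 PA + 0.1 -> intercept bmr_rate + 0.1
  ee <- energy_series(minute, 0.9 + 0.02 * pa_v + 0.1)
  pa <- activity_index(minute, pa_v, "accel")
  r <- schutz_dit(ee, pa, w, bmr = bmr)
  expect_equal(r$rmr_rate, 1.0, tolerance = 1e-10)
  expect_equal(r$total_kcal, 0.1 * n, tolerance = 1e-7)
  expect_equal(r$model$slope, 0.02, tolerance = 1e-10)

  # EE = bmr_rate at PA = 0, arbitrary slope -> zero DIT
  ee0 <- energy_series(minute, 0.9 + 0.05 * pa_v)
  expect_equal(schutz_dit(ee0, pa, w, bmr = bmr)$total_kcal, 0,
               tolerance = 1e-7)

  # intercept below the basal rate yields a negative total, retained
  ee_neg <- energy_series(minute, 0.85 + 0.02 * pa_v)
  expect_lt(schutz_dit(ee_neg, pa, w, bmr = bmr)$total_kcal, 0)

  expect_error(schutz_dit(ee, activity_index(minute, rep(7, n), "accel"),
                          w, bmr = bmr), "identical")
  expect_error(schutz_dit(ee, pa, postprandial_windows(0, 40), bmr = bmr),
               "fewer than 2")
})

test_that("bin width changes the intercept estimate on one noisy session", {
  cfg <- sim_config(seed = 404)
  sim <- simulate_session(cfg)
  s <- sim$session
  totals <- vapply(c(30, 10, 1), function(b) {
    schutz_dit(s$ee, s$accel, s$windows, bmr = s$rates$bmr,
               bin_minutes = b)$total_kcal
  }, numeric(1))
  expect_length(unique(totals), 3L)  # resolutions genuinely differ
  # re-binning oracle at 10 min: means of full bins, closed-form OLS intercept
  mins <- unlist(lapply(seq_along(s$windows$start), function(i)
    seq(s$windows$start[i], s$windows$end[i] - 1)))
  grp <- unlist(lapply(seq_along(s$windows$start), function(i) {
    m <- seq(s$windows$start[i], s$windows$end[i] - 1)
    1000 * i + (m - s$windows$start[i]) %/% 10
  }))
  ee_b <- tapply(s$ee$ee[match(mins, s$ee$minute)], grp, mean)
  pa_b <- tapply(s$accel$value[match(mins, s$accel$minute)], grp, mean)
  o <- ols_closed_form(as.numeric(pa_b), as.numeric(ee_b))
  expect_equal(totals[2],
               (o$intercept - s$rates$bmr / 1440) * s$windows$total_minutes,
               tolerance = 1e-8)
})

test_that("adding a constant to EE shifts both methods' totals by c x minutes", {
  s <- make_linear_session(n = 480, dit_rate = 0.08)
  cc <- 0.07
  ee2 <- structure(data.frame(minute = s$ee$minute, ee = s$ee$ee + cc),
                   class = c("energy_series", "data.frame"))
  mins <- s$windows$total_minutes
  # time-course method with the calibration held fixed
  model <- fit_fasting_calibration(bout_steady_means(s$ee, s$accel, s$bouts),
                                   "accel")
  eee <- estimate_ee(model, s$accel)
  t1 <- nihn_dit(s$ee, eee, s$windows)$total_kcal
  t2 <- nihn_dit(ee2, eee, s$windows)$total_kcal
  expect_equal(t2 - t1, cc * mins, tolerance = 1e-9)
  # intercept method: the constant passes through the fitted intercept
  b1 <- schutz_dit(s$ee, s$accel, s$windows, bmr = s$rates$bmr)$total_kcal
  b2 <- schutz_dit(ee2, s$accel, s$windows, bmr = s$rates$bmr)$total_kcal
  expect_equal(b2 - b1, cc * mins, tolerance = 1e-9)
  # refitting the fasting calibration on shifted EE absorbs the constant
  expect_equal(run_method(s, "M1a")$total_kcal,
               {s2 <- s; s2$ee <- ee2; run_method(s2, "M1a")$total_kcal},
               tolerance = 1e-9)
})

test_that("the intercept method is sensitive to activity timing under a varying DIT curve", {
  # same bin-level PA values, permuted so high activity coincides with high
  # DIT; the fasting-calibration estimate is unchanged, the intercept moves
  n <- 360
  minute <- 0:(n - 1)
  dit_v <- dit_response_curve(minute + 0.5, intake = 700, fraction = 0.1, tau = 60)
  pa_early <- rep(c(25, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5), each = 30)
  pa_late <- rev(pa_early)
  w <- postprandial_windows(0, n)
  bmr <- 0.9 * 1440
  tot <- vapply(list(pa_early, pa_late), function(pv) {
    ee <- energy_series(minute, 0.9 + 0.02 * pv + dit_v)
    schutz_dit(ee, activity_index(minute, pv, "accel"), w, bmr = bmr)$total_kcal
  }, numeric(1))
  expect_gt(abs(tot[1] - tot[2]), 1)
})

test_that("run_method enforces per-method prerequisites", {
  s <- make_linear_session()
  s_nobout <- s; s_nobout$bouts <- NULL
  expect_error(run_method(s_nobout, "M1a"), "calibration bouts")
  s_nob <- s; s_nob$rates <- NULL
  expect_error(run_method(s_nob, "M2a"), "basal metabolic rate")
  expect_error(run_method(s, "M1b"), "infrared")
  # all four methods on one simulated session recover the truth to tolerance
  sim <- simulate_session(sim_config(seed = 99))
  truth <- sim$truth$window_dit_kcal
  for (m in c("M1a", "M1b", "M2a", "M2b")) {
    r <- run_method(sim$session, m)
    expect_s3_class(r, "dit_result")
    expect_identical(r$method, m)
    expect_lt(abs(r$total_kcal - truth) / truth, 0.5)
  }
})
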