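# Deterministic hand-built sessions for unit tests (no simulator involved).

# A session whose EE is exactly bmr_rate + slope * accel (+ optional dit
# rate inside the windows), on an n-minute grid with four calibration bouts.
make_linear_session <- function(n = 480, bmr_rate = 0.9, slope = 0.02,
                                dit_rate = 0, accel = NULL) {
  minute <- 0:(n - 1)
  bout_starts <- c(0, 25, 50, 75)
  bouts <- lapply(seq_along(bout_starts), function(i) {
    bout_window(paste0("b", i), bout_starts[i], bout_starts[i] + 20)
  })
  if (is.null(accel)) {
    accel <- rep(5, n)
    for (i in seq_along(bout_starts)) {
      accel[minute >= bout_starts[i] & minute < bout_starts[i] + 20] <-
        c(2, 6, 10, 20)[i]
    }
    # deterministic ripple so 30-min bins have distinct PA
    accel[minute >= 100] <- 5 + 10 * ((minute[minute >= 100] %/% 30) %% 3)
  }
  windows <- postprandial_windows(100, n)
  ee <- bmr_rate + slope * accel
  ee[minute >= 100] <- ee[minute >= 100] + dit_rate
  chamber_session(
    ee = energy_series(minute, ee),
    accel = activity_index(minute, accel, "accel"),
    bouts = bouts,
    meals = data.frame(label = "meal", start = 99, intake_kcal = 700),
    windows = windows,
    rates = metabolic_rates(bmr = bmr_rate * 1440, bmr_source = "measured"),
    subject = "unit")
}

# Closed-form OLS slope/intercept (covariance / variance form), the
# independent oracle for every lm-based fit in the package.
ols_closed_form <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = sl, intercept = mean(y) - sl * mean(x))
}
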