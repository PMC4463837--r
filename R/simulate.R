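#' Configuration for a simulated chamber session
#'
#' Defines a ~24 h whole-room calorimetry stay under the additive model
#' EE(t) = basal rate + slope x activity(t) + sum of meal-locked
#' thermogenic responses + Gaussian noise. Defaults encode a
#' reproducibility-style protocol: chamber entry at t = 0 (18:50 clock
#' time), dinner 10 min in, 7 h sleep overnight, four 20-min fasting
#' calibration bouts in the morning, breakfast and lunch, and three 5-h
#' postprandial evaluation windows (15 h total). Free-living activity is
#' kept mostly below 30 mG vector magnitude, the typical intensity of
#' spontaneous movement in a chamber.
#'
#' @param seed Integer seed; `NULL` to use the current RNG state.
#' @param duration_min Session length in minutes.
#' @param bmr_rate Basal metabolic rate in kcal/min (default 0.9, i.e.
#'   1296 kcal/day).
#' @param pa_slope Activity energy cost, kcal/min per mG (default 0.02).
#' @param dit_fraction Fraction of ingested energy appearing as
#'   diet-induced thermogenesis (default 0.10, the textbook value for a
#'   mixed diet); must lie in \[0, 0.3\].
#' @param dit_tau Time-to-peak of the thermogenic response in minutes
#'   (default 60).
#' @param meals Data frame `label`, `start`, `intake_kcal`; default three
#'   meals totalling 2008 kcal.
#' @param sleep `c(start, end)` sleep interval in minutes.
#' @param bout_schedule Data frame `label`, `start`, `end`, `target_mg` for
#'   the four fasting calibration activities.
#' @param windows Data frame `start`, `end` of evaluation windows.
#' @param free_living_mean Mean free-living activity level in mG.
#' @param sleep_accel_mean Mean activity level during sleep in mG.
#' @param noise_sd_ee SD of the additive minute-EE noise, kcal/min.
#' @param ir_sat Accel level (mG) at which per-second infrared detection
#'   probability saturates at 1; probability is min(1, accel / ir_sat).
#'   The default (60) keeps percent-movement proportional to intensity
#'   across the free-living range (< 30 mG), with saturation only during
#'   sustained vigorous movement.
#' @param quantize_mg Sensor resolution applied to the simulated activity
#'   index (0 = off); real hardware resolves ~3 mG.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = NULL,
                       duration_min = 1440,
                       bmr_rate = 0.9,
                       pa_slope = 0.02,
                       dit_fraction = 0.10,
                       dit_tau = 60,
                       meals = data.frame(
                         label = c("dinner", "breakfast", "lunch"),
                         start = c(10, 840, 1140),
                         intake_kcal = c(670, 669, 669)),
                       sleep = c(310, 730),
                       bout_schedule = data.frame(
                         label = c("sitting_rest", "computer_work",
                                   "jigsaw", "laundry_folding"),
                         start = c(740, 765, 790, 815),
                         end = c(760, 785, 810, 835),
                         target_mg = c(2, 6, 10, 20)),
                       windows = data.frame(start = c(10, 840, 1140),
                                            end = c(310, 1140, 1440)),
                       free_living_mean = 8,
                       sleep_accel_mean = 0.5,
                       noise_sd_ee = 0.03,
                       ir_sat = 60,
                       quantize_mg = 0) {
  cfg <- list(seed = seed, duration_min = duration_min, bmr_rate = bmr_rate,
              pa_slope = pa_slope, dit_fraction = dit_fraction,
              dit_tau = dit_tau, meals = meals, sleep = sleep,
              bout_schedule = bout_schedule, windows = windows,
              free_living_mean = free_living_mean,
              sleep_accel_mean = sleep_accel_mean,
              noise_sd_ee = noise_sd_ee, ir_sat = ir_sat,
              quantize_mg = quantize_mg)
  if (dit_fraction < 0 || dit_fraction > 0.3) {
    stop("`dit_fraction` must lie in [0, 0.3]", call. = FALSE)
  }
  for (nm in c("bmr_rate", "pa_slope", "dit_tau", "noise_sd_ee",
               "free_living_mean", "sleep_accel_mean", "ir_sat")) {
    if (cfg[[nm]] < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
  }
  ends <- c(cfg$meals$start, cfg$sleep[2], cfg$bout_schedule$end,
            cfg$windows$end)
  if (any(ends > duration_min)) {
    stop("schedule overflows `duration_min`", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Configuration for a validity-style (fasted evaluation) session
#'
#' A chamber stay with a single evening meal, overnight sleep, the morning
#' calibration bouts, and one 6-h fasted evaluation block (08:00-14:00
#' clock time) during which the true diet-induced thermogenesis is zero —
#' the design used to test whether an estimator returns the theoretical
#' value of zero.
#'
#' @param seed,... Passed to [sim_config()]; any argument of
#'   [sim_config()] can be overridden.
#' @return A `sim_config`.
#' @export
sim_config_validity <- function(seed = NULL, ...) {
  args <- list(
    seed = seed,
    duration_min = 1160,
    dit_fraction = 0,
    meals = data.frame(label = "dinner", start = 10, intake_kcal = 802),
    sleep = c(250, 670),
    bout_schedule = data.frame(
      label = c("sitting_rest", "computer_work", "jigsaw", "laundry_folding"),
      start = c(680, 705, 730, 755),
      end = c(700, 725, 750, 775),
      target_mg = c(2, 6, 10, 20)),
    windows = data.frame(start = 790, end = 1150))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Meal-locked thermogenic response curve
#'
#' A single-peak gamma-type curve for the rate of diet-induced
#' thermogenesis t minutes after a meal:
#' d(t) = A (t / tau) exp(1 - t / tau), with A chosen so the curve
#' integrates to `fraction * intake` over (0, Inf). The peak rate A occurs
#' at t = tau; the curve is zero for t < 0.
#'
#' @param t_since_meal Minutes since the meal (vectorised).
#' @param intake Meal energy in kcal.
#' @param fraction Fraction of intake appearing as thermogenesis.
#' @param tau Time-to-peak in minutes (> 0).
#' @return Thermogenesis rate in kcal/min at each `t_since_meal`.
#' @examples
#' integrate(dit_response_curve, 0, Inf, intake = 670, fraction = 0.1,
#'           tau = 60)$value  # 67
#' @export
dit_response_curve <- function(t_since_meal, intake, fraction, tau) {
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  # mass of (t/tau) exp(1 - t/tau) over (0, Inf) is e * tau, so A = fraction*intake/(e*tau)
  a <- fraction * intake / (exp(1) * tau)
  ifelse(t_since_meal > 0,
         a * (t_since_meal / tau) * exp(1 - t_since_meal / tau),
         0)
}

quantize <- function(x, step) if (step > 0) round(x / step) * step else x

#' Simulate one chamber session with known ground truth
#'
#' Builds the minute-grid activity profile from the schedule (calibration
#' bouts at their target levels, low exponential-tailed activity while
#' awake, near-zero during sleep), composes noiseless energy expenditure as
#' basal + activity-linear + meal-locked thermogenesis, adds Gaussian noise
#' floored at zero, and renders the infrared index from per-second
#' Bernoulli detections whose probability saturates in the activity level.
#' Deterministic under a fixed `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `session` (a [chamber_session()] carrying both
#'   activity indices, the schedule, exact metabolic rates and windows) and
#'   `truth` (per-minute `bmr`, `paee`, `dit` components in kcal/min, the
#'   noiseless EE, and `window_dit_kcal`, the thermogenesis integrated over
#'   the evaluation windows).
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$duration_min
  minute <- 0:(n - 1L)

  # activity profile (mG vector magnitude, per-minute mean): spontaneous
  # movement comes in multi-minute episodes, not iid minutes — draw episode
  # lengths geometrically (mean ~10 min) with an episode-level intensity
  accel <- numeric(n)
  i <- 1L
  while (i <= n) {
    len <- 1L + stats::rgeom(1, 1 / 10)
    lvl <- stats::rexp(1, rate = 1 / cfg$free_living_mean)
    j <- min(n, i + len - 1L)
    accel[i:j] <- pmax(0, lvl + stats::rnorm(j - i + 1L, 0, 0.3))
    i <- j + 1L
  }
  asleep <- minute >= cfg$sleep[1] & minute < cfg$sleep[2]
  accel[asleep] <- stats::rexp(sum(asleep), rate = 1 / max(cfg$sleep_accel_mean, 1e-6))
  for (i in seq_len(nrow(cfg$bout_schedule))) {
    b <- cfg$bout_schedule[i, ]
    in_bout <- minute >= b$start & minute < b$end
    accel[in_bout] <- pmax(0, b$target_mg + stats::rnorm(sum(in_bout), 0, 0.5))
  }
  accel <- quantize(accel, cfg$quantize_mg)

  # additive EE composition
  bmr_min <- rep(cfg$bmr_rate, n)
  paee <- cfg$pa_slope * accel
  dit <- rep(0, n)
  for (i in seq_len(nrow(cfg$meals))) {
    m <- cfg$meals[i, ]
    dit <- dit + dit_response_curve(minute + 0.5 - m$start, m$intake_kcal,
                                    cfg$dit_fraction, cfg$dit_tau)
  }
  ee_clean <- bmr_min + paee + dit
  ee <- pmax(0, ee_clean + stats::rnorm(n, 0, cfg$noise_sd_ee))

  # infrared: 60 per-second Bernoulli detections per minute
  p_det <- pmin(1, accel / cfg$ir_sat)
  ir_pct <- 100 * stats::rbinom(n, 60L, p_det) / 60

  windows <- postprandial_windows(cfg$windows$start, cfg$windows$end,
                                  sleep = cfg$sleep)
  bouts <- lapply(seq_len(nrow(cfg$bout_schedule)), function(i) {
    bout_window(cfg$bout_schedule$label[i], cfg$bout_schedule$start[i],
                cfg$bout_schedule$end[i])
  })
  session <- chamber_session(
    ee = energy_series(minute, ee),
    accel = activity_index(minute, accel, "accel"),
    infrared = activity_index(minute, ir_pct, "infrared"),
    bouts = bouts, sleep = cfg$sleep, meals = cfg$meals, windows = windows,
    rates = metabolic_rates(bmr = cfg$bmr_rate * 1440, bmr_source = "measured"),
    subject = "sim")
  wmins <- window_minutes(windows)
  truth <- list(
    components = data.frame(minute = minute, bmr = bmr_min, paee = paee,
                            dit = dit, ee_noiseless = ee_clean),
    window_dit_kcal = sum(dit[minute %in% wmins]),
    total_dit_kcal = sum(dit))
  list(session = session, truth = truth)
}

#' Render a minute-level activity profile as a raw 32 Hz triaxial stream
#'
#' For end-to-end tests of the signal chain: each minute's target vector
#' magnitude is rendered as a body-movement sinusoid (well above the
#' high-pass cutoff) distributed over the three axes, superimposed on a
#' 1000 mG gravity component on the vertical axis. After
#' [highpass_filter()] + [synthetic_acceleration()] +
#' [aggregate_to_minutes()], the recovered minute means approximate the
#' targets.
#'
#' @param target_mg Per-minute target mean vector magnitude (mG).
#' @param sample_rate Hz (default 32).
#' @param movement_hz Frequency of the rendered movement (default 2 Hz).
#' @return A [raw_accel_stream()].
#' @export
render_raw_accel <- function(target_mg, sample_rate = 32, movement_hz = 2) {
  spm <- as.integer(sample_rate * 60)
  n <- length(target_mg) * spm
  tt <- (seq_len(n) - 1) / sample_rate
  amp <- rep(target_mg, each = spm) * pi / 2  # |a sin| has mean 2a/pi
  s <- amp * sin(2 * pi * movement_hz * tt)
  # split the movement across axes with fixed direction cosines
  raw_accel_stream(x = s * 0.6, y = s * 0.48, z = 1000 + s * sqrt(1 - 0.6^2 - 0.48^2),
                   sample_rate = sample_rate)
}

#' Simulated validity experiment: fasted-block DIT by all four methods
#'
#' Simulates `n_subjects` independent fasted-evaluation sessions (true DIT
#' zero in the evaluation block by default) and estimates DIT in the block
#' with all four methods, using each subject's exact basal rate, optionally
#' perturbed to study BMR-misspecification bias in the intercept methods.
#'
#' @param cfg A [sim_config_validity()]-style configuration.
#' @param n_subjects Number of simulated subjects.
#' @param seed Integer seed for the whole experiment.
#' @param bmr_error_kcal_day Constant added to the BMR handed to the
#'   intercept methods (0 = exact).
#' @return A data frame with columns `subject`, `M1a`, `M1b`, `M2a`, `M2b`
#'   (kcal over the evaluation block) and attribute `truth_kcal`, the mean
#'   ground-truth windowed DIT.
#' @export
validity_experiment <- function(cfg, n_subjects = 20, seed = 1,
                                bmr_error_kcal_day = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- vector("list", n_subjects)
  truths <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    cfg$seed <- (seed * 10007L + s) %% .Machine$integer.max
    sim <- simulate_session(cfg)
    rates <- metabolic_rates(bmr = cfg$bmr_rate * 1440 + bmr_error_kcal_day,
                             bmr_source = "measured")
    est <- vapply(c("M1a", "M1b", "M2a", "M2b"), function(m) {
      run_method(sim$session, m, rates = rates)$total_kcal
    }, numeric(1))
    rows[[s]] <- data.frame(subject = s, M1a = est[["M1a"]], M1b = est[["M1b"]],
                            M2a = est[["M2a"]], M2b = est[["M2b"]])
    truths[s] <- sim$truth$window_dit_kcal
  }
  out <- do.call(rbind, rows)
  attr(out, "truth_kcal") <- mean(truths)
  out
}

#' Simulated test-retest experiment: two chamber days per subject
#'
#' Simulates each subject twice with independent noise and activity
#' realisations under one protocol, estimates windowed DIT by the requested
#' method on both days, and feeds the paired columns to
#' [paired_day_stats()].
#'
#' @param cfg A [sim_config()].
#' @param n_subjects Number of simulated subjects.
#' @param seed Integer seed.
#' @param method Method id to evaluate.
#' @return A list: `day1`, `day2` (per-subject kcal), `truth_kcal`
#'   (per-subject mean ground truth), `report` (a `comparison_report`).
#' @export
reproducibility_experiment <- function(cfg, n_subjects = 15, seed = 1,
                                       method = "M1a") {
  stopifnot(inherits(cfg, "sim_config"))
  day1 <- day2 <- truth <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    est <- numeric(2)
    tr <- numeric(2)
    for (d in 1:2) {
      cfg$seed <- (seed * 20011L + 2L * s + d) %% .Machine$integer.max
      sim <- simulate_session(cfg)
      est[d] <- run_method(sim$session, method)$total_kcal
      tr[d] <- sim$truth$window_dit_kcal
    }
    day1[s] <- est[1]; day2[s] <- est[2]; truth[s] <- mean(tr)
  }
  list(day1 = day1, day2 = day2, truth_kcal = truth,
       report = paired_day_stats(day1, day2))
}
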