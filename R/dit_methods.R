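#' Postprandial evaluation windows
#'
#' The half-open minute intervals over which diet-induced thermogenesis is
#' integrated — e.g. a single 6-h fasting block for a validity protocol, or
#' three 5-h post-meal blocks for a reproducibility protocol. Windows must
#' not overlap each other, and must not intersect the sleep interval when
#' one is given (the intercept method excludes sleep by construction, and
#' the fasting-calibration method evaluates waking thermogenesis).
#'
#' @param starts,ends Numeric vectors of window starts and (exclusive) ends,
#'   minutes from session start.
#' @param sleep Optional `c(start, end)` sleep interval to check against.
#' @return An object of class `postprandial_windows` with fields `start`,
#'   `end`, `total_minutes`.
#' @export
postprandial_windows <- function(starts, ends, sleep = NULL) {
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  if (length(starts) != length(ends) || !length(starts)) {
    stop("`starts` and `ends` must be non-empty and of equal length", call. = FALSE)
  }
  if (any(ends <= starts)) stop("each window needs end > start", call. = FALSE)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (length(starts) > 1L && any(starts[-1] < ends[-length(ends)])) {
    stop("windows must not overlap", call. = FALSE)
  }
  if (!is.null(sleep)) {
    if (any(starts < sleep[2] & ends > sleep[1])) {
      stop("evaluation windows must not intersect the sleep interval", call. = FALSE)
    }
  }
  structure(list(start = starts, end = ends,
                 total_minutes = sum(ends - starts)),
            class = "postprandial_windows")
}

#' @export
print.postprandial_windows <- function(x, ...) {
  cat(sprintf("<postprandial_windows> %d window(s), %g min total\n",
              length(x$start), x$total_minutes))
  invisible(x)
}

window_minutes <- function(w) {
  unlist(lapply(seq_along(w$start),
                function(i) seq(ceiling(w$start[i]), ceiling(w$end[i]) - 1L)),
         use.names = FALSE)
}

#' Fasting-state activity calibration model
#'
#' Ordinary-least-squares regression of steady-state energy expenditure on
#' activity intensity across the fasting calibration bouts. The intercept
#' estimates the resting (zero-activity) rate in the fasted state — basal
#' metabolic rate plus any residual — and the slope converts activity-index
#' units to kcal/min. Fitted to bout-level means (typically four bouts);
#' with fasting data the prediction intercept + slope * PA is the non-DIT
#' energy expenditure EEe = BMR + PAEE.
#'
#' @param bout_means A data frame as returned by [bout_steady_means()]
#'   (columns `ee_kcal_min`, `pa_index`), or any data frame with numeric
#'   columns of those names.
#' @param pa_kind `"accel"` or `"infrared"` — which index the model maps.
#' @return An object of class `calibration_model` with fields `slope`,
#'   `intercept`, `r` (Pearson correlation of the fit), `n_points`,
#'   `pa_kind`.
#' @examples
#' bm <- data.frame(ee_kcal_min = c(1.0, 1.2, 1.4, 1.6),
#'                  pa_index = c(0, 10, 20, 30))
#' fit_fasting_calibration(bm, "accel")
#' @export
fit_fasting_calibration <- function(bout_means, pa_kind = c("accel", "infrared")) {
  pa_kind <- match.arg(pa_kind)
  stopifnot(is.data.frame(bout_means),
            all(c("ee_kcal_min", "pa_index") %in% names(bout_means)))
  ee <- bout_means$ee_kcal_min; pa <- bout_means$pa_index
  if (length(ee) < 2L) {
    stop("need at least 2 calibration bouts to fit a line", call. = FALSE)
  }
  if (length(unique(pa)) < 2L) {
    stop("all bout activity values are identical; the slope is undefined",
         call. = FALSE)
  }
  fit <- stats::lm(ee ~ pa)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(pa, ee),
                 n_points = length(ee),
                 pa_kind = pa_kind),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model:%s> EE = %.4f + %.5f * PA (r = %.3f, n = %d)\n",
              x$pa_kind, x$intercept, x$slope, x$r, x$n_points))
  invisible(x)
}

#' Predict non-thermogenic energy expenditure from activity
#'
#' Applies a fasting calibration model minute-by-minute to an activity
#' index series, giving the estimated energy expenditure EEe (basal +
#' activity-related, excluding diet-induced thermogenesis). The raw affine
#' prediction is returned without flooring at zero: in practice the
#' intercept sits at the data's origin so negative predictions do not arise,
#' and clipping would bias the DIT residual.
#'
#' @param model A [fit_fasting_calibration()] model.
#' @param pa An [activity_index()] whose kind matches `model$pa_kind`.
#' @return A data frame of class `energy_series` (columns `minute`, `ee`);
#'   unlike [energy_series()] it is not floored, values may be negative.
#' @export
estimate_ee <- function(model, pa) {
  stopifnot(inherits(model, "calibration_model"), inherits(pa, "activity_index"))
  if (index_kind(pa) != model$pa_kind) {
    stop(sprintf("activity kind '%s' does not match the model's '%s'",
                 index_kind(pa), model$pa_kind), call. = FALSE)
  }
  structure(data.frame(minute = pa$minute,
                       ee = model$intercept + model$slope * pa$value),
            class = c("energy_series", "data.frame"))
}

new_dit_result <- function(method, total_kcal, intake, time_course = NULL,
                           rmr_rate = NULL, bmr_rate = NULL, model = NULL,
                           total_minutes = NA_real_) {
  structure(list(
    method = method,
    total_kcal = total_kcal,
    percent_of_intake = if (!is.null(intake) && isTRUE(intake > 0))
      100 * total_kcal / intake else NA_real_,
    time_course = time_course,
    rmr_rate = rmr_rate,
    bmr_rate = bmr_rate,
    model = model,
    total_minutes = total_minutes
  ), class = "dit_result")
}

#' @export
print.dit_result <- function(x, ...) {
  cat(sprintf("<dit_result:%s> total %.1f kcal over %g min%s\n",
              x$method, x$total_kcal, x$total_minutes,
              if (is.na(x$percent_of_intake)) ""
              else sprintf(" (%.1f%% of intake)", x$percent_of_intake)))
  if (!is.null(x$rmr_rate)) {
    cat(sprintf("  RMR %.4f, BMR %.4f kcal/min (intercept - basal)\n",
                x$rmr_rate, x$bmr_rate))
  }
  invisible(x)
}

#' Diet-induced thermogenesis by fasting calibration (time-course method)
#'
#' DIT at minute t is the measured energy expenditure minus the
#' calibration-predicted non-thermogenic expenditure, EE(t) - EEe(t),
#' summed over the evaluation windows. Negative minutes are retained —
#' truncation at zero would bias the total, and the residual's sign is
#' itself informative. This is the only estimator that yields a
#' minute-resolution DIT time course.
#'
#' @param ee Measured [energy_series()].
#' @param eee Predicted EEe series from [estimate_ee()], on the same grid.
#' @param windows [postprandial_windows()] to integrate over.
#' @param intake Energy intake in kcal (for percent-of-intake; `NULL` to skip).
#' @param method Label recorded on the result (`"M1a"` or `"M1b"`).
#' @return A `dit_result` with `total_kcal`, `percent_of_intake` and the
#'   per-minute `time_course`.
#' @export
nihn_dit <- function(ee, eee, windows, intake = NULL, method = "M1a") {
  stopifnot(inherits(ee, "energy_series"), inherits(eee, "energy_series"),
            inherits(windows, "postprandial_windows"))
  mins <- window_minutes(windows)
  i_ee <- match(mins, ee$minute)
  i_eee <- match(mins, eee$minute)
  if (anyNA(i_ee) || anyNA(i_eee)) {
    stop("evaluation windows not fully covered by both EE and EEe series",
         call. = FALSE)
  }
  tc <- data.frame(minute = mins, dit_kcal_min = ee$ee[i_ee] - eee$ee[i_eee])
  new_dit_result(method, total_kcal = sum(tc$dit_kcal_min), intake = intake,
                 time_course = tc, total_minutes = windows$total_minutes)
}

#' Diet-induced thermogenesis by the postprandial intercept method
#'
#' The classical chamber approach: energy expenditure and activity index
#' are averaged over consecutive bins (default 30 min) inside the
#' postprandial waking windows, EE is regressed on activity across bins,
#' and the zero-activity intercept is taken as the resting metabolic rate
#' RMR = BMR + DIT rate. DIT is then (intercept - BMR/1440) kcal/min scaled
#' by the evaluation-window minutes. Bins are anchored at each window's
#' start; a partial bin at a window's end is dropped. The total can be
#' negative when the fitted intercept falls below the basal rate.
#'
#' @param ee Measured [energy_series()].
#' @param pa An [activity_index()] on the same grid.
#' @param windows [postprandial_windows()] (must exclude sleep).
#' @param bmr Basal metabolic rate in kcal/day.
#' @param bin_minutes Bin width in minutes (default 30).
#' @param intake Energy intake in kcal (optional).
#' @param method Label recorded on the result (`"M2a"` or `"M2b"`).
#' @return A `dit_result` with `total_kcal`, `rmr_rate`, `bmr_rate` and the
#'   bin-level regression as `model`; no time course.
#' @export
schutz_dit <- function(ee, pa, windows, bmr, bin_minutes = 30,
                       intake = NULL, method = "M2a") {
  stopifnot(inherits(ee, "energy_series"), inherits(pa, "activity_index"),
            inherits(windows, "postprandial_windows"),
            is.numeric(bmr), length(bmr) == 1L, bmr > 0)
  bins_ee <- numeric(0); bins_pa <- numeric(0)
  for (i in seq_along(windows$start)) {
    w0 <- ceiling(windows$start[i]); w1 <- ceiling(windows$end[i])
    n_bins <- (w1 - w0) %/% bin_minutes
    for (b in seq_len(n_bins)) {
      mins <- seq(w0 + (b - 1L) * bin_minutes, length.out = bin_minutes)
      i_ee <- match(mins, ee$minute); i_pa <- match(mins, pa$minute)
      if (anyNA(i_ee) || anyNA(i_pa)) {
        stop(sprintf("bin [%d, %d) not fully covered by both series",
                     mins[1], mins[1] + bin_minutes), call. = FALSE)
      }
      bins_ee <- c(bins_ee, mean(ee$ee[i_ee]))
      bins_pa <- c(bins_pa, mean(pa$value[i_pa]))
    }
  }
  if (length(bins_ee) < 2L) {
    stop("fewer than 2 full bins inside the evaluation windows", call. = FALSE)
  }
  if (length(unique(bins_pa)) < 2L) {
    stop("bin activity values are all identical; intercept is undefined",
         call. = FALSE)
  }
  fit <- stats::lm(bins_ee ~ bins_pa)
  rmr_rate <- unname(stats::coef(fit)[1])
  bmr_rate <- bmr / 1440
  dit_rate <- rmr_rate - bmr_rate
  model <- structure(list(slope = unname(stats::coef(fit)[2]),
                          intercept = rmr_rate,
                          r = stats::cor(bins_pa, bins_ee),
                          n_points = length(bins_ee),
                          pa_kind = index_kind(pa)),
                     class = "calibration_model")
  new_dit_result(method, total_kcal = dit_rate * windows$total_minutes,
                 intake = intake, rmr_rate = rmr_rate, bmr_rate = bmr_rate,
                 model = model, total_minutes = windows$total_minutes)
}

#' Run one of the four DIT estimation methods on a chamber session
#'
#' Dispatches across the four method labels: fasting-calibration with the
#' accelerometer index (`M1a`) or infrared index (`M1b`), and the
#' postprandial-intercept method with either index (`M2a`, `M2b`). The
#' fasting-calibration methods require the session's calibration bouts; the
#' intercept methods require a basal metabolic rate.
#'
#' @param session A [chamber_session()].
#' @param method_id One of `"M1a"`, `"M1b"`, `"M2a"`, `"M2b"`.
#' @param rates A [metabolic_rates()] with `bmr` set (required for `M2a`/
#'   `M2b`); defaults to the session's own rates.
#' @param bin_minutes Bin width for the intercept method.
#' @return A `dit_result`.
#' @export
run_method <- function(session, method_id = c("M1a", "M1b", "M2a", "M2b"),
                       rates = NULL, bin_minutes = 30) {
  method_id <- match.arg(method_id)
  stopifnot(inherits(session, "chamber_session"))
  if (is.null(rates)) rates <- session$rates
  kind <- if (endsWith(method_id, "a")) "accel" else "infrared"
  pa <- session_activity(session, kind)
  if (is.null(pa)) {
    stop(sprintf("%s requires a '%s' activity index, which the session lacks",
                 method_id, kind), call. = FALSE)
  }
  windows <- session$windows
  if (is.null(windows)) stop("session has no evaluation windows", call. = FALSE)
  if (startsWith(method_id, "M1")) {
    if (is.null(session$bouts) || !length(session$bouts)) {
      stop(sprintf("%s requires fasting calibration bouts, which the session lacks",
                   method_id), call. = FALSE)
    }
    bm <- bout_steady_means(session$ee, pa, session$bouts)
    model <- fit_fasting_calibration(bm, kind)
    eee <- estimate_ee(model, pa)
    res <- nihn_dit(session$ee, eee, windows, intake = session$intake_kcal,
                    method = method_id)
    res$model <- model
    res
  } else {
    if (is.null(rates) || is.null(rates$bmr)) {
      stop(sprintf("%s requires a basal metabolic rate (metabolic_rates(bmr = ...))",
                   method_id), call. = FALSE)
    }
    schutz_dit(session$ee, pa, windows, bmr = rates$bmr,
               bin_minutes = bin_minutes, intake = session$intake_kcal,
               method = method_id)
  }
}
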