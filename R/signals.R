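#' Raw triaxial accelerometer stream
#'
#' Container for an evenly sampled three-axis acceleration recording, as
#' produced by a waist-worn triaxial accelerometer in a metabolic chamber.
#' Axis values are in mG (1 mG = 0.001 standard gravity); an unfiltered
#' stream therefore carries a ~1000 mG gravity component split across axes.
#'
#' @param x,y,z Numeric vectors of per-sample acceleration in mG, one per
#'   axis (anteroposterior, mediolateral, vertical). Must have equal length.
#' @param sample_rate Sampling rate in Hz (default 32).
#' @param start_time Time of the first sample, in seconds from session start.
#' @return An object of class `raw_accel_stream`: a list with elements
#'   `x`, `y`, `z`, `sample_rate`, `start_time`.
#' @examples
#' s <- raw_accel_stream(x = rnorm(64), y = rnorm(64), z = 1000 + rnorm(64))
#' s$sample_rate
#' @export
raw_accel_stream <- function(x, y, z, sample_rate = 32, start_time = 0) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  if (length(x) != length(y) || length(x) != length(z)) {
    stop("all three axes must have the same length", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("acceleration samples must not contain NA", call. = FALSE)
  }
  rng <- range(c(x, y, z))
  if (rng[1] < -6000 || rng[2] > 6000) {
    stop("acceleration outside the sensor range of ±6000 mG", call. = FALSE)
  }
  structure(
    list(x = x, y = y, z = z,
         sample_rate = sample_rate, start_time = start_time),
    class = "raw_accel_stream"
  )
}

#' @export
print.raw_accel_stream <- function(x, ...) {
  cat(sprintf("<raw_accel_stream> %d samples @ %g Hz (%.1f s)\n",
              length(x$x), x$sample_rate, length(x$x) / x$sample_rate))
  invisible(x)
}

#' Per-minute activity-index series
#'
#' A minute-grid series of physical-activity intensity, either the mean
#' vector-magnitude acceleration in mG (`kind = "accel"`) or the percentage
#' of seconds per minute in which a passive-infrared motion sensor fired
#' (`kind = "infrared"`, range 0-100).
#'
#' @param minute Integer minute indices (strictly increasing) on the common
#'   session grid; the value at minute m covers the half-open interval
#'   \[m, m + 1).
#' @param value Non-negative activity values; for `kind = "infrared"` they
#'   must lie in \[0, 100\].
#' @param kind `"accel"` or `"infrared"`.
#' @return A data frame of class `activity_index` with columns `minute` and
#'   `value` and attribute `kind`.
#' @export
activity_index <- function(minute, value, kind = c("accel", "infrared")) {
  kind <- match.arg(kind)
  minute <- as.integer(minute); value <- as.numeric(value)
  if (length(minute) != length(value)) {
    stop("`minute` and `value` must have the same length", call. = FALSE)
  }
  if (length(minute) && any(diff(minute) <= 0)) {
    stop("`minute` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(value) || any(value < 0)) {
    stop("activity values must be non-negative and non-missing", call. = FALSE)
  }
  if (kind == "infrared" && any(value > 100)) {
    stop("infrared percent-movement must lie in [0, 100]", call. = FALSE)
  }
  structure(data.frame(minute = minute, value = value),
            kind = kind, class = c("activity_index", "data.frame"))
}

#' @export
print.activity_index <- function(x, ...) {
  cat(sprintf("<activity_index:%s> %d minutes [%d, %d]\n", attr(x, "kind"),
              nrow(x), if (nrow(x)) min(x$minute) else NA_integer_,
              if (nrow(x)) max(x$minute) else NA_integer_))
  invisible(x)
}

#' Kind of an activity index series
#' @param pa An `activity_index` object.
#' @return `"accel"` or `"infrared"`.
#' @export
index_kind <- function(pa) attr(pa, "kind")

#' Calibration-activity bout window
#'
#' One timed activity bout (e.g. seated rest, desk work) with its
#' steady-state sub-window. The steady window discards the first 2 minutes
#' (metabolic on-transient) and the final minute of the bout; all windows
#' are half-open \[start, end) on the minute grid, so a 20-minute bout
#' yields 17 steady one-minute samples.
#'
#' @param label Activity name.
#' @param start,end Bout start and end, in minutes from session start
#'   (`end` exclusive); the bout must be at least 4 minutes long so that a
#'   non-empty steady window exists.
#' @return An object of class `bout_window` with fields `label`, `start`,
#'   `end`, `steady_start`, `steady_end`.
#' @export
bout_window <- function(label, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  steady_start <- start + 2
  steady_end <- end - 1
  if (!(start < steady_start && steady_start < steady_end && steady_end < end)) {
    stop(sprintf("bout '%s' too short: need end - start > 3 min for a steady window",
                 label), call. = FALSE)
  }
  structure(list(label = as.character(label), start = start, end = end,
                 steady_start = steady_start, steady_end = steady_end),
            class = "bout_window")
}

#' @export
print.bout_window <- function(x, ...) {
  cat(sprintf("<bout_window> '%s' [%g, %g) steady [%g, %g)\n",
              x$label, x$start, x$end, x$steady_start, x$steady_end))
  invisible(x)
}

#' High-pass filter a raw acceleration stream
#'
#' Removes the gravitational (DC and postural) component from each axis with
#' a 4th-order Butterworth high-pass filter applied forward-backward
#' ([signal::filtfilt()]), giving zero phase shift so that filtered samples
#' stay aligned with the bout schedule. The default cutoff of 0.7 Hz is the
#' standard choice for separating body movement from gravity in waist-worn
#' accelerometry.
#'
#' @param stream A [raw_accel_stream()].
#' @param cutoff High-pass cutoff frequency in Hz; must lie in
#'   (0, sample_rate / 2).
#' @param order Butterworth filter order (default 4).
#' @return A `raw_accel_stream` of the same length with each axis filtered.
#' @examples
#' s <- raw_accel_stream(x = rep(1000, 320), y = rep(0, 320), z = rep(0, 320))
#' f <- highpass_filter(s)
#' max(abs(f$x[160:320]))  # gravity removed
#' @export
highpass_filter <- function(stream, cutoff = 0.7, order = 4) {
  stopifnot(inherits(stream, "raw_accel_stream"))
  fs <- stream$sample_rate
  if (!(cutoff > 0 && cutoff < fs / 2)) {
    stop(sprintf("`cutoff` must lie in (0, %g) Hz for a %g Hz stream",
                 fs / 2, fs), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  # filtfilt's edge padding needs ~3 filter lengths of data
  min_len <- 3L * (max(length(bf$b), length(bf$a)) - 1L) + 1L
  if (length(stream$x) < min_len) {
    stop(sprintf("stream too short for the filter transient: need >= %d samples, got %d",
                 min_len, length(stream$x)), call. = FALSE)
  }
  raw_accel_stream(
    x = signal::filtfilt(bf, stream$x),
    y = signal::filtfilt(bf, stream$y),
    z = signal::filtfilt(bf, stream$z),
    sample_rate = fs, start_time = stream$start_time
  )
}

#' Vector-magnitude (synthetic) acceleration
#'
#' Per-sample Euclidean norm of the three high-pass-filtered axes, in mG.
#' This is the scalar activity-intensity signal that both thermogenesis
#' estimators calibrate against.
#'
#' @param stream A high-pass filtered [raw_accel_stream()].
#' @return Numeric vector of per-sample magnitudes (>= 0), same length as
#'   each axis.
#' @examples
#' s <- raw_accel_stream(x = 3, y = 4, z = 0, sample_rate = 1)
#' synthetic_acceleration(s)  # 5
#' @export
synthetic_acceleration <- function(stream) {
  stopifnot(inherits(stream, "raw_accel_stream"))
  sqrt(stream$x^2 + stream$y^2 + stream$z^2)
}

#' Aggregate a magnitude series to the minute grid
#'
#' Arithmetic mean of the per-sample magnitude over consecutive epochs
#' (default 60 s), producing the per-minute accelerometer activity index.
#' A partial trailing epoch is dropped rather than averaged over fewer
#' samples.
#'
#' @param magnitude Numeric vector of per-sample magnitudes (mG).
#' @param sample_rate Samples per second of `magnitude`.
#' @param epoch Epoch length in seconds (default 60).
#' @param start_minute Minute index assigned to the first full epoch.
#' @return An [activity_index()] with `kind = "accel"`.
#' @export
aggregate_to_minutes <- function(magnitude, sample_rate = 32, epoch = 60,
                                 start_minute = 0) {
  if (!length(magnitude)) stop("empty magnitude series", call. = FALSE)
  spe <- sample_rate * epoch
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch must span a whole number of samples", call. = FALSE)
  }
  spe <- as.integer(round(spe))
  n_epochs <- length(magnitude) %/% spe
  if (n_epochs < 1L) {
    stop(sprintf("series shorter than one epoch (%d samples needed, got %d)",
                 spe, length(magnitude)), call. = FALSE)
  }
  used <- magnitude[seq_len(n_epochs * spe)]
  means <- colMeans(matrix(used, nrow = spe))
  activity_index(minute = start_minute + seq_len(n_epochs) - 1L,
                 value = means, kind = "accel")
}

#' Per-minute infrared percent-movement
#'
#' Collapses per-second hit flags from one or more passive-infrared motion
#' sensors to the minute grid: a second counts as positive when at least one
#' sensor fired, and the minute value is the percentage of its 60 seconds
#' that were positive.
#'
#' @param hits A data frame with columns `time_s` (integer second), `sensor_id`
#'   and `hit` (0/1), or a logical/0-1 matrix with one row per second and one
#'   column per sensor (rows taken as consecutive seconds from `start_s`).
#' @param start_s First second covered when `hits` is a matrix.
#' @return An [activity_index()] with `kind = "infrared"`. Every minute in
#'   the covered span must have all 60 seconds reported; a gap is an error
#'   (no imputation).
#' @export
infrared_minute_percent <- function(hits, start_s = 0) {
  if (is.matrix(hits)) {
    sec <- start_s + seq_len(nrow(hits)) - 1L
    pos <- rowSums(hits != 0) > 0
  } else {
    stopifnot(is.data.frame(hits),
              all(c("time_s", "sensor_id", "hit") %in% names(hits)))
    agg <- tapply(hits$hit != 0, hits$time_s, any)
    sec <- as.integer(names(agg))
    o <- order(sec)
    sec <- sec[o]; pos <- as.logical(agg)[o]
  }
  if (!length(sec)) stop("no infrared data", call. = FALSE)
  min_idx <- sec %/% 60L
  cnt <- table(min_idx)
  if (any(cnt != 60L)) {
    bad <- names(cnt)[cnt != 60L]
    stop(sprintf("minute(s) %s have missing seconds (need all 60; no imputation)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  pct <- 100 * tapply(pos, min_idx, mean)
  activity_index(minute = as.integer(names(pct)), value = as.numeric(pct),
                 kind = "infrared")
}

#' Steady-state bout means of energy expenditure and activity
#'
#' For each calibration bout, averages the minute-grid energy expenditure
#' and activity index over the bout's steady-state window
#' \[start + 2, end - 1), excluding the metabolic on-transient and the
#' final transition minute.
#'
#' @param ee An [energy_series()] (kcal/min on the minute grid).
#' @param pa An [activity_index()] on the same grid.
#' @param bouts A list of [bout_window()] objects.
#' @return A data frame with one row per bout: `label`, `ee_kcal_min`,
#'   `pa_index`, `n_minutes`.
#' @export
bout_steady_means <- function(ee, pa, bouts) {
  stopifnot(inherits(ee, "energy_series"), inherits(pa, "activity_index"))
  if (inherits(bouts, "bout_window")) bouts <- list(bouts)
  rows <- lapply(bouts, function(b) {
    stopifnot(inherits(b, "bout_window"))
    mins <- seq(ceiling(b$steady_start), ceiling(b$steady_end) - 1L)
    i_ee <- match(mins, ee$minute)
    i_pa <- match(mins, pa$minute)
    if (anyNA(i_ee) || anyNA(i_pa)) {
      stop(sprintf("bout '%s': steady window [%g, %g) not fully covered by both series",
                   b$label, b$steady_start, b$steady_end), call. = FALSE)
    }
    data.frame(label = b$label,
               ee_kcal_min = mean(ee$ee[i_ee]),
               pa_index = mean(pa$value[i_pa]),
               n_minutes = length(mins))
  })
  do.call(rbind, rows)
}
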