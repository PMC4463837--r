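#' One subject-day chamber session
#'
#' Bundles every aligned series and schedule element needed to estimate
#' diet-induced thermogenesis for one subject over one chamber stay: the
#' minute-grid energy expenditure, one or both activity indices, the
#' fasting calibration bouts, the sleep interval, the meal schedule and the
#' evaluation windows. All present series must share the same minute grid,
#' every schedule element must lie inside the session span, and evaluation
#' windows must not intersect sleep.
#'
#' @param ee An [energy_series()], or a [gas_series()] which is converted
#'   via [weir_ee()].
#' @param accel Optional [activity_index()] of kind `"accel"`.
#' @param infrared Optional [activity_index()] of kind `"infrared"`.
#' @param bouts Optional list of [bout_window()] calibration bouts.
#' @param sleep Optional `c(start, end)` sleep interval, minutes.
#' @param meals Optional data frame with columns `label`, `start`,
#'   `intake_kcal`.
#' @param windows Optional [postprandial_windows()]; re-validated against
#'   `sleep`.
#' @param rates Optional [metabolic_rates()].
#' @param subject Subject identifier.
#' @return An object of class `chamber_session`.
#' @export
chamber_session <- function(ee, accel = NULL, infrared = NULL, bouts = NULL,
                            sleep = NULL, meals = NULL, windows = NULL,
                            rates = NULL, subject = "S1") {
  if (inherits(ee, "gas_series")) ee <- weir_ee(ee)
  stopifnot(inherits(ee, "energy_series"))
  grid <- ee$minute
  for (nm in c("accel", "infrared")) {
    pa <- get(nm)
    if (!is.null(pa)) {
      stopifnot(inherits(pa, "activity_index"))
      if (index_kind(pa) != nm) {
        stop(sprintf("`%s` must be an activity_index of kind '%s'", nm, nm),
             call. = FALSE)
      }
      if (!identical(pa$minute, grid)) {
        stop(sprintf("`%s` is not on the session's minute grid", nm),
             call. = FALSE)
      }
    }
  }
  span <- c(min(grid), max(grid) + 1L)
  in_span <- function(a, b) a >= span[1] && b <= span[2]
  if (!is.null(sleep)) {
    stopifnot(length(sleep) == 2L, sleep[1] < sleep[2])
    if (!in_span(sleep[1], sleep[2])) {
      stop("sleep interval lies outside the session span", call. = FALSE)
    }
  }
  if (!is.null(bouts)) {
    if (inherits(bouts, "bout_window")) bouts <- list(bouts)
    for (b in bouts) {
      stopifnot(inherits(b, "bout_window"))
      if (!in_span(b$start, b$end)) {
        stop(sprintf("bout '%s' lies outside the session span", b$label),
             call. = FALSE)
      }
    }
  }
  if (!is.null(meals)) {
    stopifnot(is.data.frame(meals),
              all(c("label", "start", "intake_kcal") %in% names(meals)))
    if (nrow(meals) && !all(meals$start >= span[1] & meals$start < span[2])) {
      stop("meal time outside the session span", call. = FALSE)
    }
  }
  if (!is.null(windows)) {
    stopifnot(inherits(windows, "postprandial_windows"))
    # re-validate against sleep so a session can never carry a window/sleep overlap
    windows <- postprandial_windows(windows$start, windows$end, sleep = sleep)
    if (!in_span(min(windows$start), max(windows$end))) {
      stop("evaluation window outside the session span", call. = FALSE)
    }
  }
  intake <- if (!is.null(meals) && nrow(meals)) sum(meals$intake_kcal) else NULL
  structure(list(subject = subject, ee = ee, accel = accel,
                 infrared = infrared, bouts = bouts, sleep = sleep,
                 meals = meals, windows = windows, rates = rates,
                 intake_kcal = intake),
            class = "chamber_session")
}

#' @export
print.chamber_session <- function(x, ...) {
  cat(sprintf("<chamber_session> subject %s, %d min\n", x$subject, nrow(x$ee)))
  cat(sprintf("  indices: %s | bouts: %d | meals: %d | windows: %s\n",
              paste(c(if (!is.null(x$accel)) "accel",
                      if (!is.null(x$infrared)) "infrared",
                      if (is.null(x$accel) && is.null(x$infrared)) "none"),
                    collapse = "+"),
              if (is.null(x$bouts)) 0L else length(x$bouts),
              if (is.null(x$meals)) 0L else nrow(x$meals),
              if (is.null(x$windows)) "none"
              else sprintf("%g min", x$windows$total_minutes)))
  invisible(x)
}

#' Retrieve one of a session's activity indices
#' @param session A [chamber_session()].
#' @param kind `"accel"` or `"infrared"`.
#' @return The [activity_index()] or `NULL` if absent.
#' @export
session_activity <- function(session, kind = c("accel", "infrared")) {
  kind <- match.arg(kind)
  session[[kind]]
}

write_delim_full <- function(df, path) {
  df_chr <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) ifelse(is.na(col), "NA", sprintf("%.17g", col))
    else as.character(col)
  }), stringsAsFactors = FALSE)
  names(df_chr) <- names(df)
  utils::write.table(df_chr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_delim_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a chamber session to a directory of delimited text files
#'
#' One directory holds one subject-session: `ee.tsv` (minute_index,
#' ee_kcal_min), `activity_accel.tsv` / `activity_infrared.tsv`
#' (minute_index, value), `events.tsv` (event_type, label, start, end,
#' intake_kcal), and `rates.tsv` when metabolic rates are set. Numeric
#' columns are written at full double precision so that a write-read round
#' trip is lossless.
#'
#' @param session A [chamber_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "chamber_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_delim_full(data.frame(minute_index = session$ee$minute,
                              ee_kcal_min = session$ee$ee),
                   file.path(dir, "ee.tsv"))
  for (kind in c("accel", "infrared")) {
    pa <- session[[kind]]
    if (!is.null(pa)) {
      write_delim_full(data.frame(minute_index = pa$minute, value = pa$value),
                       file.path(dir, paste0("activity_", kind, ".tsv")))
    }
  }
  ev <- data.frame(event_type = character(0), label = character(0),
                   start = numeric(0), end = numeric(0),
                   intake_kcal = numeric(0))
  if (!is.null(session$meals) && nrow(session$meals)) {
    ev <- rbind(ev, data.frame(event_type = "meal", label = session$meals$label,
                               start = session$meals$start, end = session$meals$start,
                               intake_kcal = session$meals$intake_kcal))
  }
  if (!is.null(session$sleep)) {
    ev <- rbind(ev, data.frame(event_type = "sleep", label = "sleep",
                               start = session$sleep[1], end = session$sleep[2],
                               intake_kcal = NA_real_))
  }
  if (!is.null(session$bouts)) {
    for (b in session$bouts) {
      ev <- rbind(ev, data.frame(event_type = "bout", label = b$label,
                                 start = b$start, end = b$end,
                                 intake_kcal = NA_real_))
    }
  }
  if (!is.null(session$windows)) {
    ev <- rbind(ev, data.frame(event_type = "window",
                               label = paste0("W", seq_along(session$windows$start)),
                               start = session$windows$start,
                               end = session$windows$end,
                               intake_kcal = NA_real_))
  }
  write_delim_full(ev, file.path(dir, "events.tsv"))
  if (!is.null(session$rates)) {
    rt <- session$rates
    write_delim_full(data.frame(
      key = c("smr", "bmr", "bmr_source", "subject"),
      value = c(if (is.null(rt$smr)) "" else sprintf("%.17g", rt$smr),
                if (is.null(rt$bmr)) "" else sprintf("%.17g", rt$bmr),
                rt$bmr_source, session$subject)),
      file.path(dir, "rates.tsv"))
  } else {
    write_delim_full(data.frame(key = "subject", value = session$subject),
                     file.path(dir, "rates.tsv"))
  }
  invisible(dir)
}

#' Load a chamber session from a directory
#'
#' Reads the files written by [write_session()] (or prepared by hand in the
#' same layout) and assembles a validated [chamber_session()]. When
#' `ee.tsv` is absent but `gas.tsv` (minute_index, vo2_l_min, vco2_l_min)
#' is present, energy expenditure is derived with [weir_ee()].
#'
#' @param dir Session directory.
#' @return A [chamber_session()].
#' @export
load_session <- function(dir) {
  ee_path <- file.path(dir, "ee.tsv")
  gas_path <- file.path(dir, "gas.tsv")
  if (file.exists(ee_path)) {
    d <- read_delim_file(ee_path)
    ee <- energy_series(d$minute_index, d$ee_kcal_min)
  } else if (file.exists(gas_path)) {
    d <- read_delim_file(gas_path)
    ee <- weir_ee(gas_series(d$minute_index, d$vo2_l_min, d$vco2_l_min))
  } else {
    stop(sprintf("no ee.tsv or gas.tsv in '%s'", dir), call. = FALSE)
  }
  pa <- list(accel = NULL, infrared = NULL)
  for (kind in c("accel", "infrared")) {
    p <- file.path(dir, paste0("activity_", kind, ".tsv"))
    if (file.exists(p)) {
      d <- read_delim_file(p)
      pa[[kind]] <- activity_index(d$minute_index, d$value, kind)
    }
  }
  meals <- NULL; sleep <- NULL; bouts <- NULL; windows <- NULL
  ev_path <- file.path(dir, "events.tsv")
  if (file.exists(ev_path)) {
    ev <- read_delim_file(ev_path)
    if (nrow(ev)) {
      m <- ev[ev$event_type == "meal", , drop = FALSE]
      if (nrow(m)) meals <- data.frame(label = m$label, start = m$start,
                                       intake_kcal = m$intake_kcal)
      s <- ev[ev$event_type == "sleep", , drop = FALSE]
      if (nrow(s)) sleep <- c(s$start[1], s$end[1])
      b <- ev[ev$event_type == "bout", , drop = FALSE]
      if (nrow(b)) bouts <- lapply(seq_len(nrow(b)), function(i) {
        bout_window(b$label[i], b$start[i], b$end[i])
      })
      w <- ev[ev$event_type == "window", , drop = FALSE]
      if (nrow(w)) windows <- postprandial_windows(w$start, w$end, sleep = sleep)
    }
  }
  rates <- NULL; subject <- basename(dir)
  rt_path <- file.path(dir, "rates.tsv")
  if (file.exists(rt_path)) {
    rt <- read_delim_file(rt_path)
    kv <- stats::setNames(as.character(rt$value), rt$key)
    if (!is.na(kv["subject"]) && nzchar(kv["subject"])) subject <- kv[["subject"]]
    smr <- if (!is.na(kv["smr"]) && nzchar(kv["smr"])) as.numeric(kv[["smr"]]) else NULL
    bmr <- if (!is.na(kv["bmr"]) && nzchar(kv["bmr"])) as.numeric(kv[["bmr"]]) else NULL
    if (!is.null(smr) || !is.null(bmr)) {
      src <- if (!is.na(kv["bmr_source"]) && nzchar(kv["bmr_source"]))
        kv[["bmr_source"]] else "measured"
      rates <- metabolic_rates(smr = smr, bmr = bmr, bmr_source = src)
    }
  }
  chamber_session(ee, accel = pa$accel, infrared = pa$infrared, bouts = bouts,
                  sleep = sleep, meals = meals, windows = windows,
                  rates = rates, subject = subject)
}

#' Run the full estimation pipeline on a session
#'
#' Applies each requested method to the session and, when a second (repeat)
#' session is supplied, computes the day-1 vs day-2 reproducibility report
#' for each method shared by both days. Every fitted calibration (slope,
#' intercept, r, n) is carried on the results so implausible or negative
#' DIT values can be audited.
#'
#' @param session A [chamber_session()].
#' @param methods Character vector of method ids.
#' @param session2 Optional repeat-day [chamber_session()].
#' @param bin_minutes Bin width for the intercept methods.
#' @param out_dir Optional directory: results are also written as
#'   delimited text (`dit_results.tsv`, plus `dit_timecourse_<id>.tsv`
#'   for the time-course methods).
#' @return A list with `results` (named list of `dit_result`), `table`
#'   (one row per method) and, when `session2` is given, `day2_results`
#'   and `comparison` (per-method n = 1 differences; for cohort-level
#'   reproducibility use [paired_day_stats()] across subjects).
#' @export
run_pipeline <- function(session, methods = c("M1a", "M1b", "M2a", "M2b"),
                         session2 = NULL, bin_minutes = 30, out_dir = NULL) {
  run_all <- function(s) {
    res <- lapply(methods, function(m) run_method(s, m, bin_minutes = bin_minutes))
    names(res) <- methods
    res
  }
  results <- run_all(session)
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, total_kcal = r$total_kcal,
               percent_of_intake = r$percent_of_intake,
               rmr_rate = if (is.null(r$rmr_rate)) NA_real_ else r$rmr_rate,
               slope = if (is.null(r$model)) NA_real_ else r$model$slope,
               intercept = if (is.null(r$model)) NA_real_ else r$model$intercept,
               r = if (is.null(r$model)) NA_real_ else r$model$r,
               n_points = if (is.null(r$model)) NA_integer_ else r$model$n_points)
  }))
  rownames(tab) <- NULL
  out <- list(results = results, table = tab)
  if (!is.null(session2)) {
    out$day2_results <- run_all(session2)
    out$comparison <- data.frame(
      method = methods,
      day1 = vapply(results, function(r) r$total_kcal, numeric(1)),
      day2 = vapply(out$day2_results, function(r) r$total_kcal, numeric(1)))
    out$comparison$difference <- out$comparison$day1 - out$comparison$day2
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_delim_full(tab, file.path(out_dir, "dit_results.tsv"))
    for (r in results) {
      if (!is.null(r$time_course)) {
        write_delim_full(r$time_course,
                         file.path(out_dir, sprintf("dit_timecourse_%s.tsv", r$method)))
      }
    }
    if (!is.null(session2)) {
      write_delim_full(out$comparison, file.path(out_dir, "day_comparison.tsv"))
    }
  }
  out
}
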