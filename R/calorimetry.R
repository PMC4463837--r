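#' Minute-grid gas-exchange series
#'
#' Oxygen uptake and carbon dioxide production from the open-circuit
#' chamber, both in L/min on the common minute grid.
#'
#' @param minute Integer minute indices, strictly increasing.
#' @param vo2,vco2 Non-negative rates in L/min.
#' @return A data frame of class `gas_series`.
#' @export
gas_series <- function(minute, vo2, vco2) {
  minute <- as.integer(minute)
  vo2 <- as.numeric(vo2); vco2 <- as.numeric(vco2)
  if (length(minute) != length(vo2) || length(vo2) != length(vco2)) {
    stop("`minute`, `vo2` and `vco2` must have equal length", call. = FALSE)
  }
  if (length(minute) && any(diff(minute) <= 0)) {
    stop("`minute` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(vo2) || anyNA(vco2) || any(vo2 < 0) || any(vco2 < 0)) {
    stop("gas-exchange rates must be non-negative and non-missing", call. = FALSE)
  }
  structure(data.frame(minute = minute, vo2 = vo2, vco2 = vco2),
            class = c("gas_series", "data.frame"))
}

#' Minute-grid energy-expenditure series
#'
#' @param minute Integer minute indices, strictly increasing; the value at
#'   minute m covers \[m, m + 1).
#' @param ee Energy expenditure in kcal/min, non-negative.
#' @return A data frame of class `energy_series` with columns `minute`, `ee`.
#' @export
energy_series <- function(minute, ee) {
  minute <- as.integer(minute); ee <- as.numeric(ee)
  if (length(minute) != length(ee)) {
    stop("`minute` and `ee` must have the same length", call. = FALSE)
  }
  if (length(minute) && any(diff(minute) <= 0)) {
    stop("`minute` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(ee) || any(ee < 0)) {
    stop("energy expenditure must be non-negative and non-missing", call. = FALSE)
  }
  structure(data.frame(minute = minute, ee = ee),
            class = c("energy_series", "data.frame"))
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series> %d minutes, mean %.3f kcal/min\n",
              nrow(x), if (nrow(x)) mean(x$ee) else NA_real_))
  invisible(x)
}

#' Energy expenditure by the Weir equation
#'
#' Converts gas exchange to energy expenditure with the abbreviated Weir
#' equation, EE = 3.941 VO2 + 1.106 VCO2 (kcal, gas rates in L/min). The
#' urinary-nitrogen protein correction is omitted, as is usual when no
#' urine collection accompanies the chamber session; the coefficients can
#' be overridden for other calorimetric conventions.
#'
#' @param gas A [gas_series()].
#' @param coef_o2,coef_co2 Caloric coefficients (kcal per L of O2 / CO2).
#' @return An [energy_series()] on the same minute grid.
#' @examples
#' weir_ee(gas_series(0, vo2 = 0.25, vco2 = 0.20))$ee  # 1.20655 kcal/min
#' @export
weir_ee <- function(gas, coef_o2 = 3.941, coef_co2 = 1.106) {
  stopifnot(inherits(gas, "gas_series"))
  energy_series(gas$minute, coef_o2 * gas$vo2 + coef_co2 * gas$vco2)
}

#' Sleeping metabolic rate
#'
#' The minimum energy expenditure sustained over any 3 consecutive hours of
#' sleep: the window-mean EE is computed for every 180-minute window (slid
#' in 1-minute steps) inside the sleep interval, and the minimum mean is
#' scaled to kcal/day.
#'
#' @param ee An [energy_series()] covering the full sleep interval.
#' @param sleep Numeric length-2 vector `c(start, end)` in minutes from
#'   session start, half-open \[start, end); must span at least 180 min.
#' @return SMR in kcal/day.
#' @export
sleeping_metabolic_rate <- function(ee, sleep) {
  stopifnot(inherits(ee, "energy_series"), length(sleep) == 2L)
  start <- sleep[1]; end <- sleep[2]
  if (end - start < 180) {
    stop("sleep interval must span at least 3 h (180 min)", call. = FALSE)
  }
  mins <- seq(ceiling(start), ceiling(end) - 1L)
  idx <- match(mins, ee$minute)
  if (anyNA(idx)) {
    stop("sleep interval not fully covered by the EE series (gaps are not imputed)",
         call. = FALSE)
  }
  x <- ee$ee[idx]
  cs <- c(0, cumsum(x))
  n <- length(x)
  win_sums <- cs[(180 + 1):(n + 1)] - cs[1:(n - 180 + 1)]
  min(win_sums) / 180 * 1440
}

#' Predict basal metabolic rate from sleeping metabolic rate
#'
#' Affine prediction BMR = intercept + slope * SMR using coefficients from
#' an externally fitted population model. No default coefficients are
#' shipped: prediction models are population-specific, so the coefficients
#' must be supplied (or a directly measured BMR used instead via
#' [metabolic_rates()]).
#'
#' @param smr Sleeping metabolic rate in kcal/day.
#' @param slope,intercept Model coefficients (required).
#' @return Predicted BMR in kcal/day.
#' @export
predict_bmr <- function(smr, slope, intercept) {
  if (missing(slope) || missing(intercept) ||
      is.null(slope) || is.null(intercept)) {
    stop(paste("no BMR prediction coefficients supplied:",
               "provide `slope` and `intercept`, or supply a measured BMR",
               "via metabolic_rates(bmr = ..., bmr_source = \"measured\")"),
         call. = FALSE)
  }
  intercept + slope * smr
}

#' Resting metabolic quantities for one subject-session
#'
#' @param smr Sleeping metabolic rate, kcal/day (optional).
#' @param bmr Basal metabolic rate, kcal/day.
#' @param bmr_source `"measured"` or `"predicted"`.
#' @return An object of class `metabolic_rates`.
#' @export
metabolic_rates <- function(smr = NULL, bmr = NULL,
                            bmr_source = c("measured", "predicted")) {
  bmr_source <- match.arg(bmr_source)
  for (v in list(smr = smr, bmr = bmr)) {
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v <= 0)) {
      stop("metabolic rates must be single positive numbers (kcal/day)",
           call. = FALSE)
    }
  }
  structure(list(smr = smr, bmr = bmr, bmr_source = bmr_source),
            class = "metabolic_rates")
}

#' @export
print.metabolic_rates <- function(x, ...) {
  cat(sprintf("<metabolic_rates> SMR %s, BMR %s kcal/day (%s)\n",
              if (is.null(x$smr)) "-" else sprintf("%.0f", x$smr),
              if (is.null(x$bmr)) "-" else sprintf("%.0f", x$bmr),
              x$bmr_source))
  invisible(x)
}
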