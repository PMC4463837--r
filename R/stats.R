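#' Mean and sample SD of a per-subject DIT column
#'
#' @param values Numeric vector of per-subject DIT totals (kcal/period).
#' @return Named list `mean`, `sd` (n - 1 denominator).
#' @export
column_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need n >= 2 for a sample SD", call. = FALSE)
  list(mean = mean(values), sd = stats::sd(values))
}

#' One-sample t-test against a theoretical value
#'
#' Used for the validity design: under a fasted evaluation block the true
#' diet-induced thermogenesis is zero, so per-subject estimates are tested
#' against `mu0 = 0`.
#'
#' @param values Numeric vector, n >= 2.
#' @param mu0 Null value (default 0).
#' @return List `t`, `p` (two-sided), `ci95` (length-2), `mean`, `n`.
#'   With zero variance, `p` is 1 when the mean equals `mu0` and 0
#'   otherwise (degenerate-evidence convention), with a +/-0 CI at the mean.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  m <- mean(values)
  if (stats::sd(values) == 0) {
    return(list(t = if (m == mu0) 0 else Inf * sign(m - mu0),
                p = as.numeric(m == mu0), ci95 = c(m, m), mean = m, n = n))
  }
  tt <- stats::t.test(values, mu = mu0)
  list(t = unname(tt$statistic), p = tt$p.value,
       ci95 = as.numeric(tt$conf.int), mean = m, n = n)
}

#' Count strictly negative values
#'
#' Negative per-subject DIT estimates flag a failure mode of the intercept
#' method (fitted intercept below the basal rate).
#'
#' @param values Numeric vector.
#' @return Integer count of values < 0.
#' @export
count_negative <- function(values) sum(as.numeric(values) < 0)

#' Variance-homogeneity F-test between two method columns
#'
#' F is the larger sample variance over the smaller, with a two-sided p
#' from the F distribution and a Bonferroni adjustment for the family of
#' pairwise comparisons (4 methods give 6 pairs, the default family size).
#'
#' @param a,b Numeric vectors (n >= 2 each, non-zero variance).
#' @param n_comparisons Bonferroni family size (default 6).
#' @return List `F`, `df` (numerator, denominator), `p_raw`, `p_adjusted`.
#' @export
variance_homogeneity <- function(a, b, n_comparisons = 6) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 in both columns", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0) stop("zero variance in a column; F undefined", call. = FALSE)
  if (va >= vb) {
    f <- va / vb; df <- c(length(a) - 1L, length(b) - 1L)
  } else {
    f <- vb / va; df <- c(length(b) - 1L, length(a) - 1L)
  }
  p_raw <- min(1, 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE))
  list(F = f, df = df, p_raw = p_raw,
       p_adjusted = min(1, p_raw * n_comparisons))
}

#' Within-subject coefficient of variation for paired days
#'
#' Test-retest CV in percent: the SD of the per-subject day-1 minus day-2
#' differences, divided by sqrt(2) to convert a difference SD into a
#' single-measurement within-subject SD, relative to the grand mean of all
#' measurements.
#'
#' @param day1,day2 Per-subject values, same subjects in the same order.
#' @return CV in percent.
#' @export
within_subject_cv <- function(day1, day2) {
  day1 <- as.numeric(day1); day2 <- as.numeric(day2)
  if (length(day1) != length(day2)) stop("days differ in length", call. = FALSE)
  if (length(day1) < 2L) stop("need n >= 2", call. = FALSE)
  gm <- mean(c(day1, day2))
  if (gm == 0) stop("grand mean is zero; CV undefined", call. = FALSE)
  100 * (stats::sd(day1 - day2) / sqrt(2)) / gm
}

#' Day-1 vs day-2 reproducibility report
#'
#' The full test-retest battery for one quantity measured on two chamber
#' days: mean and SD of the per-subject differences (day 1 - day 2), a
#' paired t-test, Pearson correlation between days, Bland-Altman bias with
#' +/- 2 SD limits of agreement (the coefficient of repeatability), and the
#' within-subject CV.
#'
#' With degenerate input (zero variance on a day, or identical days) the
#' correlation is reported as `NA` and flagged in `notes`; a zero-variance
#' difference vector gives paired p of 1 (bias 0) or 0 (bias non-zero).
#'
#' @param day1,day2 Per-subject values, same subjects in the same order,
#'   n >= 3.
#' @return A list of class `comparison_report`: `n`, `mean_day1`,
#'   `mean_day2`, `mean_diff`, `sd_diff`, `paired_t_p`, `pearson_r`,
#'   `pearson_p`, `bland_altman` (list `bias`, `lower`, `upper`),
#'   `cv_percent`, `notes`.
#' @export
paired_day_stats <- function(day1, day2) {
  day1 <- as.numeric(day1); day2 <- as.numeric(day2)
  if (length(day1) != length(day2)) stop("days differ in length", call. = FALSE)
  n <- length(day1)
  if (n < 3L) stop("need n >= 3 for the correlation", call. = FALSE)
  d <- day1 - day2
  mean_diff <- mean(d); sd_diff <- stats::sd(d)
  notes <- character(0)
  if (sd_diff == 0) {
    paired_p <- as.numeric(mean_diff == 0)
    notes <- c(notes, "zero variance of differences; paired p degenerate")
  } else {
    paired_p <- stats::t.test(day1, day2, paired = TRUE)$p.value
  }
  if (stats::sd(day1) == 0 || stats::sd(day2) == 0) {
    r <- NA_real_; r_p <- NA_real_
    notes <- c(notes, "zero variance on a day; correlation undefined")
  } else {
    ct <- stats::cor.test(day1, day2)
    r <- unname(ct$estimate); r_p <- ct$p.value
  }
  structure(list(
    n = n,
    mean_day1 = mean(day1), mean_day2 = mean(day2),
    mean_diff = mean_diff, sd_diff = sd_diff,
    paired_t_p = paired_p,
    pearson_r = r, pearson_p = r_p,
    bland_altman = list(bias = mean_diff,
                        lower = mean_diff - 2 * sd_diff,
                        upper = mean_diff + 2 * sd_diff),
    cv_percent = within_subject_cv(day1, day2),
    notes = notes
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> n = %d\n", x$n))
  cat(sprintf("  day1 %.2f, day2 %.2f; diff %.2f +/- %.2f (paired p = %.3g)\n",
              x$mean_day1, x$mean_day2, x$mean_diff, x$sd_diff, x$paired_t_p))
  cat(sprintf("  r = %s; Bland-Altman %.2f [%.2f, %.2f]; CV %.1f%%\n",
              if (is.na(x$pearson_r)) "NA" else sprintf("%.3f", x$pearson_r),
              x$bland_altman$bias, x$bland_altman$lower, x$bland_altman$upper,
              x$cv_percent))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}
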