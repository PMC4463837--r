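#' Reference validity-study DIT table
#'
#' Per-subject diet-induced thermogenesis over a 6-h fasted evaluation
#' block (kcal/6 h) for 11 chamber subjects, estimated by the four methods:
#' fasting-calibration with the accelerometer (`M1a`) or infrared (`M1b`)
#' index, and the postprandial-intercept method with either index (`M2a`,
#' `M2b`). Under a fast the theoretical DIT is zero, so this table is the
#' standard worked example for the validity statistics battery
#' ([column_summary()], [one_sample_t()], [count_negative()],
#' [variance_homogeneity()]).
#'
#' @return A data frame with columns `subject`, `M1a`, `M1b`, `M2a`, `M2b`.
#' @examples
#' tab <- validity_dit_reference()
#' column_summary(tab$M1a)
#' @export
validity_dit_reference <- function() {
  utils::read.delim(system.file("extdata", "validity_dit_6h.tsv",
                                package = "ditchamber"))
}
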