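#' Follow-up and pattern-group counts the generator defaults emulate
#'
#' Numerator/denominator pairs describing the availability structure of
#' the motivating cohort design: infant weight at 24 months available
#' for 3666 of 5526 children, the ~11-month weight for 746 of the 1860
#' without it, the 6-month weight for 169 of the remaining 1114, and
#' complete fetal biometry for 2287 of 3205; plus the sizes of the nine
#' combined fetal-by-infant growth-pattern groups among the 2370
#' pattern-classifiable children. The generator's default availability
#' rates ([sim_config()]) are these fractions; [count_percentages()]
#' turns the counts into the percentages they imply.
#'
#' @format A list with elements `availability` (data frame: item, k, n)
#'   and `pattern_groups` (named integer vector over the nine levels).
#' @export
reference_cohort_counts <- list(
  availability = data.frame(
    item = c("weight_24mo", "weight_11mo_given_no_24mo",
             "weight_6mo_given_neither", "fetal_biometry_complete"),
    k = c(3666L, 746L, 169L, 2287L),
    n = c(5526L, 1860L, 1114L, 3205L)),
  pattern_groups = c(
    "deceleration/deceleration" = 78L, "deceleration/normal" = 261L,
    "deceleration/acceleration" = 263L, "normal/deceleration" = 213L,
    "normal/normal" = 533L, "normal/acceleration" = 271L,
    "acceleration/deceleration" = 319L, "acceleration/normal" = 316L,
    "acceleration/acceleration" = 116L))

#' Percentages implied by count data
#'
#' @param k Numerators (successes).
#' @param n Denominators; a single total is recycled.
#' @param digits Rounding, default 1 (percent printed to one decimal).
#' @return Percentages, `100 * k / n`.
#' @export
count_percentages <- function(k, n, digits = 1L) {
  if (any(n <= 0)) stop_eg("denominators must be positive")
  round(100 * k / n, digits)
}
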