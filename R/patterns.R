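#' Centile-crossing threshold for growth acceleration/deceleration
#'
#' A change in weight SDS of more than 0.67 between two ages corresponds
#' to upward crossing of a full centile band on standard growth charts and
#' defines growth acceleration; less than -0.67 defines deceleration.
#' @export
sds_change_threshold <- 0.67

growth_levels <- c("deceleration", "normal", "acceleration")

#' Change in SDS between two ages
#'
#' @param sds_from,sds_to SDS at the earlier and later age.
#' @return `sds_to - sds_from`; missing inputs propagate.
#' @export
delta_sds <- function(sds_from, sds_to) sds_to - sds_from

#' Classify an SDS change as deceleration / normal / acceleration
#'
#' Strictly more than `threshold` is acceleration, strictly less than
#' `-threshold` deceleration; changes of exactly +/- the threshold are
#' normal ("more than" is read strictly).
#'
#' @param delta SDS change.
#' @param threshold Positive cutoff, default [sds_change_threshold].
#' @return Factor with levels deceleration, normal, acceleration.
#' @export
classify_change <- function(delta, threshold = sds_change_threshold) {
  stopifnot(threshold > 0)
  out <- ifelse(is.na(delta), NA_character_,
                ifelse(delta > threshold, "acceleration",
                       ifelse(delta < -threshold, "deceleration", "normal")))
  factor(out, levels = growth_levels)
}

#' Select the infant weight SDS with the 24-11-6 month fallback
#'
#' Infant weight change is measured to 24 months when available; otherwise
#' to the ~11-month visit, otherwise to the ~6-month visit. Returns the
#' selected SDS and the source tag.
#'
#' @param sds_24m,sds_11m,sds_6m SDS vectors (any may be `NA`).
#' @return Data frame with columns `sds` and `source`
#'   (factor: `24mo`, `11mo`, `6mo`; `NA` if none available).
#' @export
select_infant_weight <- function(sds_24m, sds_11m, sds_6m) {
  n <- max(length(sds_24m), length(sds_11m), length(sds_6m))
  sds_24m <- rep_len(sds_24m, n); sds_11m <- rep_len(sds_11m, n)
  sds_6m <- rep_len(sds_6m, n)
  src <- ifelse(!is.na(sds_24m), "24mo",
                ifelse(!is.na(sds_11m), "11mo",
                       ifelse(!is.na(sds_6m), "6mo", NA_character_)))
  val <- ifelse(!is.na(sds_24m), sds_24m,
                ifelse(!is.na(sds_11m), sds_11m, sds_6m))
  data.frame(sds = val, source = factor(src, levels = c("24mo", "11mo", "6mo")))
}

#' Combined 9-level fetal-by-infant growth pattern
#'
#' Crosses the fetal (second trimester to birth) and infant (birth to the
#' selected infant age) growth categories into nine levels, with
#' `normal/normal` as the reference level.
#'
#' @param fetal,infant Factors (or characters) with levels deceleration /
#'   normal / acceleration.
#' @return Factor with 9 levels `"<fetal>/<infant>"`, reference first.
#' @export
combined_pattern <- function(fetal, infant) {
  fetal <- factor(as.character(fetal), levels = growth_levels)
  infant <- factor(as.character(infant), levels = growth_levels)
  lab <- ifelse(is.na(fetal) | is.na(infant), NA_character_,
                paste(as.character(fetal), as.character(infant), sep = "/"))
  all9 <- as.vector(outer(growth_levels, growth_levels,
                          function(f, i) paste(f, i, sep = "/")))
  ref <- "normal/normal"
  factor(lab, levels = c(ref, setdiff(all9, ref)))
}

#' Per-child growth pattern table for a cohort
#'
#' Computes fetal and infant SDS changes, their categories, the infant
#' source age under the fallback rule, and the combined 9-level pattern.
#'
#' @param efw2_sds Second-trimester estimated-fetal-weight SDS.
#' @param birth_sds Birth-weight SDS.
#' @param sds_6m,sds_11m,sds_24m Infant weight SDS.
#' @param id Optional child identifiers.
#' @param threshold Centile-crossing cutoff, default
#'   [sds_change_threshold].
#' @return Data frame: id, fetal_delta, fetal_category, infant_delta,
#'   infant_category, infant_source, pattern.
#' @export
pattern_table <- function(efw2_sds, birth_sds, sds_6m, sds_11m, sds_24m,
                          id = seq_along(birth_sds),
                          threshold = sds_change_threshold) {
  inf <- select_infant_weight(sds_24m, sds_11m, sds_6m)
  fetal_delta <- delta_sds(efw2_sds, birth_sds)
  infant_delta <- delta_sds(birth_sds, inf$sds)
  fetal_cat <- classify_change(fetal_delta, threshold)
  infant_cat <- classify_change(infant_delta, threshold)
  data.frame(id = id,
             fetal_delta = fetal_delta, fetal_category = fetal_cat,
             infant_delta = infant_delta, infant_category = infant_cat,
             infant_source = inf$source,
             pattern = combined_pattern(fetal_cat, infant_cat))
}
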