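cohort_mandatory_cols <- c(
  "id", "sex", "child_age", "ga_birth", "birth_weight_g",
  "child_height_cm", "child_weight_kg")

cohort_factor_levels <- list(
  sex = c("girl", "boy"), education = c("higher", "lower"),
  smoking = c("no", "yes"), folic_acid = c("no", "yes"),
  parity = c("nulliparous", "multiparous"),
  ethnicity = c("European", "non-European"),
  breastfeeding = c("never", "ever"))

#' Read a cohort table from delimited text
#'
#' Reads the one-row-per-child wide table written by [write_cohort()] (or
#' assembled to the same column dictionary), restores factor codings, and
#' runs unit-plausibility checks: birth weight must look like grams,
#' infant and childhood weights like kilograms. Implausible magnitudes
#' are a hard error (no silent unit conversion); unknown columns warn and
#' are kept.
#'
#' @param path Path to a CSV file with '.' as decimal point and empty
#'   fields for missing values.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (nrow(x) == 0L) stop_eg("empty cohort file: ", path)
  miss <- setdiff(cohort_mandatory_cols, names(x))
  if (length(miss))
    stop_eg("cohort file lacks mandatory columns: ",
            paste(miss, collapse = ", "))
  known <- c(cohort_mandatory_cols, names(cohort_factor_levels),
             "maternal_age", "prepreg_bmi",
             paste0(rep(c("ga_", "hc_", "ac_", "fl_"), 2),
                    rep(c("2tri", "3tri"), each = 4)),
             paste0(rep(c("age_", "weight_", "length_"), 6),
                    rep(c("2w", "1m", "3m", "6m", "11m", "24m"), each = 3)),
             "fat_mass_kg", "fat_free_mass_kg", "visceral_fat_vol_ml",
             "pericardial_fat_vol_ml", paste0("liver_fat_s", 1:4),
             grep("^true_", names(x), value = TRUE))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    warning("unknown cohort columns kept as-is: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  for (v in names(cohort_factor_levels)) if (v %in% names(x)) {
    lev <- cohort_factor_levels[[v]]
    bad <- !is.na(x[[v]]) & !x[[v]] %in% lev
    if (any(bad))
      stop_eg("column '", v, "' has values outside {",
              paste(lev, collapse = ", "), "}")
    x[[v]] <- factor(x[[v]], levels = lev)
  }
  check_unit <- function(col, lo, hi, unit) {
    v <- x[[col]]
    if (is.null(v)) return(invisible())
    md <- stats::median(v, na.rm = TRUE)
    if (is.finite(md) && (md < lo || md > hi))
      stop_eg("column '", col, "' has median ", signif(md, 4),
              ", implausible for ", unit,
              "; check units (no silent conversion is applied)")
  }
  check_unit("birth_weight_g", 500, 6000, "grams")
  for (v in paste0("weight_", c("1m", "3m", "6m", "11m", "24m")))
    check_unit(v, 1, 30, "kilograms")
  check_unit("child_weight_kg", 10, 120, "kilograms")
  check_unit("child_height_cm", 80, 200, "centimetres")
  x
}
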