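#' Fit the per-occasion reference charts for a cohort
#'
#' Internally constructed reference charts, one per measurement occasion:
#' estimated fetal weight in the second and third trimester (log scale,
#' gestational-age-adjusted, not sex-adjusted), birth weight (by
#' gestational age and sex), and infant weight at the ~6-, ~11- and
#' ~24-month visits (by exact age and sex).
#'
#' @param cohort Cohort data frame.
#' @param n_bins,min_per_bin Passed to [fit_reference()].
#' @return Named list of `ref_chart` objects: `efw2`, `efw3`, `birth`,
#'   `w6`, `w11`, `w24`.
#' @export
cohort_charts <- function(cohort, n_bins = 3L, min_per_bin = 50L) {
  efw2 <- estimated_fetal_weight(cohort$hc_2tri, cohort$ac_2tri,
                                 cohort$fl_2tri)
  efw3 <- estimated_fetal_weight(cohort$hc_3tri, cohort$ac_3tri,
                                 cohort$fl_3tri)
  list(
    efw2 = fit_reference(cohort$ga_2tri, efw2, transform = "log",
                         n_bins = n_bins, min_per_bin = min_per_bin,
                         axis = "gestational-weeks", measure = "efw2",
                         margin = 2),
    efw3 = fit_reference(cohort$ga_3tri, efw3, transform = "log",
                         n_bins = n_bins, min_per_bin = min_per_bin,
                         axis = "gestational-weeks", measure = "efw3",
                         margin = 2),
    birth = fit_reference(cohort$ga_birth, cohort$birth_weight_g,
                          sex = cohort$sex, n_bins = n_bins,
                          min_per_bin = min_per_bin,
                          axis = "gestational-weeks", measure = "birth",
                          margin = 8),
    w6 = fit_reference(cohort$age_6m, cohort$weight_6m, sex = cohort$sex,
                       n_bins = n_bins, min_per_bin = min_per_bin,
                       measure = "w6", margin = 1.5),
    w11 = fit_reference(cohort$age_11m, cohort$weight_11m,
                        sex = cohort$sex, n_bins = n_bins,
                        min_per_bin = min_per_bin, measure = "w11",
                        margin = 2),
    w24 = fit_reference(cohort$age_24m, cohort$weight_24m,
                        sex = cohort$sex, n_bins = n_bins,
                        min_per_bin = min_per_bin, measure = "w24",
                        margin = 3))
}

#' Weight SDS at every occasion for a cohort
#'
#' @param cohort Cohort data frame.
#' @param charts Result of [cohort_charts()] (fitted on `cohort` if
#'   omitted).
#' @return Data frame with columns `efw2_sds`, `efw3_sds`, `birth_sds`,
#'   `w6_sds`, `w11_sds`, `w24_sds`.
#' @export
cohort_sds <- function(cohort, charts = cohort_charts(cohort)) {
  efw2 <- estimated_fetal_weight(cohort$hc_2tri, cohort$ac_2tri,
                                 cohort$fl_2tri)
  efw3 <- estimated_fetal_weight(cohort$hc_3tri, cohort$ac_3tri,
                                 cohort$fl_3tri)
  data.frame(
    efw2_sds = sds(efw2, cohort$ga_2tri, charts$efw2),
    efw3_sds = sds(efw3, cohort$ga_3tri, charts$efw3),
    birth_sds = sds(cohort$birth_weight_g, cohort$ga_birth, charts$birth,
                    sex = cohort$sex),
    w6_sds = sds(cohort$weight_6m, cohort$age_6m, charts$w6,
                 sex = cohort$sex),
    w11_sds = sds(cohort$weight_11m, cohort$age_11m, charts$w11,
                  sex = cohort$sex),
    w24_sds = sds(cohort$weight_24m, cohort$age_24m, charts$w24,
                  sex = cohort$sex))
}

#' Long-format infant trajectory observations
#'
#' Stacks the ~1-, ~3-, ~6-, ~11- and ~24-month visits into one row per
#' observation with age in months and years, weight, length and BMI —
#' the input for [fit_reed1()] and [fit_logbmi_cubic()].
#'
#' @param cohort Cohort data frame.
#' @return Data frame: child, sex, age_months, age, weight, bmi.
#' @export
cohort_long_weights <- function(cohort) {
  visits <- c("2w", "1m", "3m", "6m", "11m", "24m")
  out <- do.call(rbind, lapply(visits, function(v) {
    data.frame(child = cohort$id, sex = cohort$sex,
               age_months = cohort[[paste0("age_", v)]],
               weight = cohort[[paste0("weight_", v)]],
               length = cohort[[paste0("length_", v)]])
  }))
  out <- out[!is.na(out$age_months) & !is.na(out$weight), , drop = FALSE]
  out$age <- out$age_months / 12
  out$bmi <- ifelse(!is.na(out$length) & out$length > 0,
                    bmi(out$weight, out$length), NA)
  out
}

#' Childhood body-composition table for the outcome panel
#'
#' Applies the measurement derivations (volume-to-mass at 0.9 g/mL,
#' liver-sample averaging) to the childhood visit columns.
#' @param cohort Cohort data frame.
#' @return Data frame suitable for [build_outcomes()].
#' @export
cohort_body_composition <- function(cohort) {
  liver <- apply(as.matrix(cohort[, paste0("liver_fat_s", 1:4)]), 1,
                 function(s) if (all(is.na(s))) NA_real_ else
                   liver_fat_fraction(s))
  data.frame(
    height_cm = cohort$child_height_cm, weight_kg = cohort$child_weight_kg,
    fat_mass_kg = cohort$fat_mass_kg,
    fat_free_mass_kg = cohort$fat_free_mass_kg,
    visceral_fat_g = fat_volume_to_mass(cohort$visceral_fat_vol_ml),
    pericardial_fat_g = fat_volume_to_mass(cohort$pericardial_fat_vol_ml),
    liver_fat_pct = liver)
}

#' Run the full growth-pattern analysis pipeline
#'
#' Orchestrates every stage on one cohort: reference charts and SDS;
#' centile-crossing pattern classification with the infant fallback rule;
#' conditional growth variables; Reed1 and cubic log-BMI trajectory
#' models with derived peak weight velocity and adiposity peak;
#' allometric outcome panel; chained-equation imputation of missing
#' covariates; and the association models (conditional critical-period,
#' 9-level pattern contrasts, fetal-by-infant interaction, and
#' birth-size-stratified models of PWV/BMIAP/AGEAP), pooled across
#' imputations by Rubin's rules. Deterministic given the cohort and
#' `seed`.
#'
#' @param cohort A cohort data frame ([simulate_cohort()] or
#'   [read_cohort()]).
#' @param outcomes Outcome SDS columns to model; default the three MRI
#'   fat outcomes.
#' @param m Number of imputed covariate datasets, default 5.
#' @param seed Seed for the imputation draws.
#' @param charts Optional list of external reference charts (as from
#'   [generating_charts()] or [read_chart()]); by default charts are
#'   fitted internally on the cohort itself.
#' @param n_bins,min_per_bin Internal reference-chart resolution.
#' @param trajectory_method Passed to the trajectory fitters.
#' @param outdir Optional directory; results are also written as CSV.
#' @return Object of class `growth_pipeline`: list with the per-stage
#'   tables, pooled model results, and a stage log of inclusion counts.
#' @export
run_pipeline <- function(cohort,
                         outcomes = c("visceral_index_sds",
                                      "liver_fat_pct_sds",
                                      "pericardial_index_sds"),
                         m = 5L, seed = 1L, charts = NULL,
                         n_bins = 3L, min_per_bin = 50L,
                         trajectory_method = "mixed",
                         outdir = NULL) {
  log <- list(n_children = nrow(cohort))

  if (is.null(charts))
    charts <- cohort_charts(cohort, n_bins = n_bins,
                            min_per_bin = min_per_bin)
  sdsmat <- cohort_sds(cohort, charts)
  log$n_birth_sds <- sum(!is.na(sdsmat$birth_sds))

  patt <- pattern_table(sdsmat$efw2_sds, sdsmat$birth_sds,
                        sdsmat$w6_sds, sdsmat$w11_sds, sdsmat$w24_sds,
                        id = cohort$id)
  log$n_pattern <- sum(!is.na(patt$pattern))
  log$pattern_counts <- table(patt$pattern)

  cond <- conditional_variables(
    sdsmat[, c("efw2_sds", "efw3_sds", "birth_sds",
               "w6_sds", "w11_sds", "w24_sds")])
  log$n_conditional <- attr(cond, "n_eligible")

  long <- cohort_long_weights(cohort)
  reed <- fit_reed1(long[, c("child", "sex", "age", "weight")],
                    method = trajectory_method)
  pwv <- peak_weight_velocity(reed)
  cubic <- fit_logbmi_cubic(
    data.frame(child = long$child, sex = long$sex,
               age = long$age_months, bmi = long$bmi),
    method = trajectory_method)
  peak <- adiposity_peak(cubic)
  log$n_trajectory <- nrow(reed$children)

  body <- cohort_body_composition(cohort)
  panel <- build_outcomes(body)
  log$n_outcomes <- colSums(!is.na(panel[, paste0(
    c("visceral_index", "liver_fat_pct", "pericardial_index"), "_sds")]))

  birth_size <- classify_birth_size(sdsmat$birth_sds)
  log$birth_size_counts <- table(birth_size)

  analysis <- cbind(cohort[, c("id", "sex", "child_age", "maternal_age",
                               "education", "prepreg_bmi", "smoking",
                               "folic_acid", "parity", "ethnicity",
                               "breastfeeding", "birth_weight_g")],
                    sdsmat, panel,
                    patt[, c("fetal_delta", "infant_delta", "pattern")],
                    cond,
                    pwv = pwv$pwv[match(cohort$id, pwv$child)],
                    ageap = peak$ageap[match(cohort$id, peak$child)],
                    bmiap = peak$bmiap[match(cohort$id, peak$child)],
                    birth_size = birth_size)

  imp_covs <- setdiff(covariate_sets$main, c("child_age", "sex"))
  imps <- impute_covariates(analysis, imp_covs, m = m, seed = seed)

  res_cond <- do.call(rbind, lapply(outcomes, function(oc) {
    per_imp <- lapply(imps, function(d) {
      rows <- lapply(names(cond), function(cn)
        fit_association(d, oc, cn, covariate_sets$main,
                        model = "conditional"))
      do.call(rbind, rows)
    })
    pool_rubin(per_imp)
  }))

  res_patt <- do.call(rbind, lapply(outcomes, function(oc)
    pooled_association(imps, outcome = oc, exposure = "pattern",
                       covariates = covariate_sets$main,
                       model = "pattern")))

  res_int <- data.frame(
    outcome = outcomes,
    p = vapply(outcomes, function(oc)
      interaction_test(analysis, oc), numeric(1)))

  res_strat <- do.call(rbind, lapply(imps, function(d)
    stratified_infant_models(d, outcomes)))
  keyable <- !is.na(res_strat$estimate)
  res_strat <- if (any(keyable))
    pool_rubin(res_strat[keyable, setdiff(names(res_strat), "skipped")])
  else res_strat

  out <- structure(list(charts = charts, sds = sdsmat, patterns = patt,
                        conditional = cond,
                        trajectories = list(reed1 = reed, pwv = pwv,
                                            cubic = cubic, peak = peak),
                        outcomes = panel, analysis = analysis,
                        results = list(conditional = res_cond,
                                       pattern = res_patt,
                                       interaction = res_int,
                                       stratified = res_strat),
                        log = log),
                   class = "growth_pipeline")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res_cond, file.path(outdir, "conditional.csv"),
                     row.names = FALSE)
    utils::write.csv(res_patt, file.path(outdir, "patterns.csv"),
                     row.names = FALSE)
    utils::write.csv(res_int, file.path(outdir, "interaction.csv"),
                     row.names = FALSE)
    utils::write.csv(res_strat, file.path(outdir, "stratified.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis, file.path(outdir, "analysis_table.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.growth_pipeline <- function(x, ...) {
  cat("Growth-pattern analysis pipeline\n")
  cat("  children:", x$log$n_children, "\n")
  cat("  with combined pattern:", x$log$n_pattern, "\n")
  cat("  pattern counts:\n")
  print(x$log$pattern_counts)
  cat("  conditional-eligible n per time point:\n")
  print(x$log$n_conditional)
  cat("  birth size:\n")
  print(x$log$birth_size_counts)
  invisible(x)
}
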