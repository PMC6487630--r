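#' Covariate sets used by the association models
#'
#' `basic`: child age at visit and sex. `main`: basic plus family-based
#' sociodemographic factors (maternal age, educational level), maternal
#' lifestyle factors (prepregnancy BMI, smoking, folic acid use, parity)
#' and childhood factors (ethnicity, breastfeeding). `stratified_main`:
#' main plus birth weight, used in the birth-size-stratified models.
#'
#' @format Named list of character vectors of column names.
#' @export
covariate_sets <- local({
  basic <- c("child_age", "sex")
  main <- c(basic, "maternal_age", "education", "prepreg_bmi", "smoking",
            "folic_acid", "parity", "ethnicity", "breastfeeding")
  list(basic = basic, main = main,
       stratified_main = c(main, "birth_weight_g"))
})

#' @keywords internal
fit_lm_term <- function(formula, data, term, model = "main",
                        exposure = term, outcome = "outcome",
                        stratum = "all", conf_level = 0.95) {
  n <- nrow(data)
  fit <- stats::lm(formula, data = data)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    bad <- names(co)[is.na(co)]
    stop_eg("rank-deficient model; aliased columns: ",
            paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  idx <- grep(paste0("^", gsub("([.|()\\^{}+$*?\\[\\]])", "\\\\\\1", term)),
              rownames(sm))
  if (length(idx) == 0L) stop_eg("term '", term, "' not found in model")
  df <- fit$df.residual
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  out <- data.frame(outcome = outcome, exposure = exposure,
                    level = rownames(sm)[idx], stratum = stratum,
                    model = model,
                    estimate = sm[idx, 1], se = sm[idx, 2],
                    ci_low = sm[idx, 1] - tq * sm[idx, 2],
                    ci_high = sm[idx, 1] + tq * sm[idx, 2],
                    p = sm[idx, 4], n = n, df = df, pooled = FALSE,
                    row.names = NULL)
  out
}

#' Fit one association model
#'
#' Ordinary least squares of an outcome SDS on an exposure plus a covariate
#' set, with confidence intervals and p-values from the t distribution on
#' residual degrees of freedom. Factor exposures (e.g. the 9-level combined
#' growth pattern) yield one contrast per non-reference level. Rows with
#' any missing model variable are dropped (use [impute_covariates()] and
#' [pool_rubin()] for the imputation-based analysis).
#'
#' @param data Data frame holding outcome, exposure and covariates.
#' @param outcome Name of the outcome column (SDS scale).
#' @param exposure Name of the exposure column (numeric, or factor for
#'   pattern contrasts).
#' @param covariates Character vector of covariate column names, e.g.
#'   `covariate_sets$main`; missing columns error.
#' @param model Tag recorded in the result.
#' @param stratum Tag recorded in the result.
#' @param min_n Minimum rows (beyond parameters + 10) to fit.
#' @return Data frame of association results, one row per exposure term.
#' @export
fit_association <- function(data, outcome, exposure,
                            covariates = covariate_sets$main,
                            model = "main", stratum = "all",
                            min_n = NULL) {
  miss <- setdiff(c(outcome, exposure, covariates), names(data))
  if (length(miss))
    stop_eg("columns not in data: ", paste(miss, collapse = ", "))
  d <- data[, c(outcome, exposure, covariates), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (is.factor(d[[exposure]])) d[[exposure]] <- droplevels(d[[exposure]])
  # covariates that are constant on the analysis sample (common in small
  # strata) carry no adjustment information and would break the fit
  constant <- vapply(covariates, function(v) {
    x <- d[[v]]
    if (is.factor(x) || is.character(x))
      length(unique(as.character(x))) < 2L
    else isTRUE(stats::sd(x) == 0)
  }, logical(1))
  covariates <- covariates[!constant]
  p_par <- length(covariates) + 2L +
    if (is.factor(d[[exposure]])) nlevels(d[[exposure]]) - 2L else 0L
  need <- max(p_par + 10L, min_n %||% 0L)
  if (nrow(d) < need)
    stop_eg("only ", nrow(d), " complete rows; need at least ", need)
  fml <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit_lm_term(fml, d, term = exposure, model = model,
              exposure = exposure, outcome = outcome, stratum = stratum)
}

#' Wald test for a fetal-by-infant growth interaction
#'
#' Tests the product term between continuous fetal and infant SDS change
#' in a model containing both main effects plus child age and sex
#' (the basic adjustment used for the interaction assessment).
#'
#' @param data Data frame with columns `fetal_delta`, `infant_delta`, the
#'   outcome, and the basic covariates.
#' @param outcome Name of the outcome SDS column.
#' @param covariates Covariates, default `covariate_sets$basic`.
#' @return Two-sided p-value for the interaction term.
#' @export
interaction_test <- function(data, outcome,
                             covariates = covariate_sets$basic) {
  need <- c("fetal_delta", "infant_delta", outcome, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_eg("columns not in data: ", paste(miss, collapse = ", "))
  d <- data[, need, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < length(need) + 10L)
    stop_eg("too few complete rows (", nrow(d), ") for interaction test")
  fml <- stats::reformulate(
    c("fetal_delta * infant_delta", covariates), response = outcome)
  r <- fit_lm_term(fml, d, term = "fetal_delta:infant_delta",
                   model = "interaction", outcome = outcome)
  r$p
}

#' Birth-size-stratified models of infant growth measures
#'
#' Within each birth-size stratum (SGA, AGA, LGA), regresses each outcome
#' SDS on peak weight velocity, BMI at adiposity peak and age at adiposity
#' peak (each in a separate model), adjusted for the stratified covariate
#' set (main covariates plus birth weight). Strata below `min_stratum_n`
#' are flagged and skipped, not fitted.
#'
#' @param data Data frame with a `birth_size` factor (SGA/AGA/LGA),
#'   exposure columns, outcome columns and covariates.
#' @param outcomes Character vector of outcome SDS columns.
#' @param exposures Character vector of growth-measure columns, default
#'   `c("pwv", "bmiap", "ageap")`.
#' @param covariates Default `covariate_sets$stratified_main`.
#' @param min_stratum_n Minimum stratum size, default 30.
#' @return Data frame of association results; skipped strata appear with
#'   `NA` estimates and `skipped = TRUE`.
#' @export
stratified_infant_models <- function(data, outcomes,
                                     exposures = c("pwv", "bmiap", "ageap"),
                                     covariates =
                                       covariate_sets$stratified_main,
                                     min_stratum_n = 30L) {
  if (!"birth_size" %in% names(data)) stop_eg("data lacks 'birth_size'")
  res <- list()
  for (st in levels(factor(data$birth_size))) {
    d <- data[!is.na(data$birth_size) & data$birth_size == st, ,
              drop = FALSE]
    for (ex in exposures) for (oc in outcomes) {
      cc <- sum(stats::complete.cases(d[, c(oc, ex, covariates)]))
      if (cc < min_stratum_n) {
        res[[length(res) + 1L]] <- data.frame(
          outcome = oc, exposure = ex, level = ex, stratum = st,
          model = "stratified_main", estimate = NA_real_, se = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, p = NA_real_, n = cc,
          df = NA_real_, pooled = FALSE, skipped = TRUE)
        next
      }
      r <- fit_association(d, oc, ex, covariates,
                           model = "stratified_main", stratum = st)
      r$skipped <- FALSE
      res[[length(res) + 1L]] <- r
    }
  }
  do.call(rbind, res)
}

#' Pool association results across imputed datasets by Rubin's rules
#'
#' Point estimate is the mean of the per-imputation estimates; total
#' variance is the mean within-imputation variance plus `(1 + 1/m)` times
#' the between-imputation variance. Confidence intervals and p-values use
#' the t distribution with Barnard-Rubin small-sample degrees of freedom.
#' With a single imputation (or zero between-variance) pooling reduces to
#' the complete-data inference.
#'
#' @param results Data frame of per-imputation results as returned by
#'   [fit_association()] (one row per imputation, same outcome/exposure/
#'   level/model), or a list of such frames which are pooled row-wise.
#' @param conf_level Confidence level, default 0.95.
#' @return One pooled result row (or one per distinct term).
#' @export
pool_rubin <- function(results, conf_level = 0.95) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  key <- interaction(results$outcome, results$exposure, results$level,
                     results$stratum, results$model, drop = TRUE)
  if (length(unique(table(key))) > 1L)
    stop_eg("mismatched specs: unequal numbers of imputations per term")
  pooled <- lapply(split(results, key), function(r) {
    m <- nrow(r)
    qbar <- mean(r$estimate)
    ubar <- mean(r$se^2)
    b <- if (m > 1L) stats::var(r$estimate) else 0
    tot <- ubar + (1 + 1 / m) * b
    dfcom <- mean(r$df)
    if (b > 0 && m > 1L) {
      riv <- (1 + 1 / m) * b / ubar
      lambda <- (1 + 1 / m) * b / tot
      df_old <- (m - 1) / lambda^2
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- df_old * df_obs / (df_old + df_obs)
    } else df <- dfcom
    se <- sqrt(tot)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df)
    out <- r[1, , drop = FALSE]
    out$estimate <- qbar; out$se <- se
    out$ci_low <- qbar - tq * se; out$ci_high <- qbar + tq * se
    out$p <- 2 * stats::pt(abs(qbar / se), df, lower.tail = FALSE)
    out$df <- df; out$pooled <- TRUE
    out
  })
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out
}
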