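pattern_label_order <- c(
  "normal/normal",
  "deceleration/deceleration", "deceleration/normal",
  "deceleration/acceleration", "normal/deceleration",
  "normal/acceleration", "acceleration/deceleration",
  "acceleration/normal", "acceleration/acceleration")

default_effect_map <- list(
  visceral = c("deceleration/deceleration" = -0.01,
               "deceleration/normal" = -0.22,
               "deceleration/acceleration" = 0.18,
               "normal/deceleration" = -0.08,
               "normal/normal" = 0,
               "normal/acceleration" = 0.07,
               "acceleration/deceleration" = -0.08,
               "acceleration/normal" = 0.08,
               "acceleration/acceleration" = 0.05),
  liver = c("deceleration/deceleration" = -0.06,
            "deceleration/normal" = -0.06,
            "deceleration/acceleration" = 0.34,
            "normal/deceleration" = -0.11,
            "normal/normal" = 0,
            "normal/acceleration" = 0.09,
            "acceleration/deceleration" = -0.06,
            "acceleration/normal" = 0.03,
            "acceleration/acceleration" = -0.08),
  pericardial = c("deceleration/deceleration" = -0.07,
                  "deceleration/normal" = -0.08,
                  "deceleration/acceleration" = -0.09,
                  "normal/deceleration" = 0.05,
                  "normal/normal" = 0,
                  "normal/acceleration" = -0.07,
                  "acceleration/deceleration" = 0.15,
                  "acceleration/normal" = 0.08,
                  "acceleration/acceleration" = 0.08))

default_missing_rates <- list(
  fetal_full = 0.714,   # both trimesters measured
  w24 = 0.663,          # 24-month weight available
  w11_given_no24 = 0.401,
  w6_given_neither = 0.152,
  w11_with_w24 = 0.75,  # joint availability among followed-up children
  w6_with_later = 0.80,
  early_visits = 0.85,  # 1- and 3-month trajectory visits
  dxa = 0.97,
  visceral = 0.852, liver = 0.954, pericardial = 0.886)

default_covariate_missing <- c(
  maternal_age = 0, education = 0.078, prepreg_bmi = 0.15,
  smoking = 0.204, folic_acid = 0.312, parity = 0.036,
  ethnicity = 0.020, breastfeeding = 0.155)

default_covariate_effects <- list(
  smoking = 0.10, prepreg_bmi = 0.12, education = 0.05,
  breastfeeding = -0.05)

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates everything [simulate_cohort()] needs: cohort
#' size, seed, the tracking correlation of the latent weight-SDS process,
#' the true pattern-to-outcome effects, covariate effects, availability
#' rates, and the generating growth curves. Defaults emulate the data
#' structure of a population-based birth cohort followed from
#' mid-pregnancy to age ten: tracking correlation 0.7 between consecutive
#' weight SDS; 24-month weight available for 66.3%, the ~11-month weight
#' for 40.1% of those without it, and the 6-month weight for 15.2% of the
#' remainder; complete fetal biometry for 71.4%; and a liver-fat effect of
#' 0.34 SDS for fetal deceleration followed by infant acceleration (with
#' the remaining pattern effects on visceral, liver and pericardial fat
#' at correspondingly realistic values).
#'
#' @param n_children Number of children, at least 1.
#' @param seed Integer master seed; fixes the cohort exactly.
#' @param tracking_rho Correlation between consecutive latent weight SDS,
#'   in (-1, 1).
#' @param effect_map Named list outcome -> named vector of true effects
#'   (outcome-SDS units) over the nine `fetal/infant` pattern levels.
#'   Outcomes: `visceral`, `liver`, `pericardial`, `fmi`, `ffmi`.
#' @param covariate_effects Named list covariate -> effect in outcome-SDS
#'   units (binary covariates: per exposed level; `prepreg_bmi`: per SD).
#' @param conditional_effects Optional named list outcome -> named vector
#'   of effects of the standardized AR innovations at
#'   `c("t2tri","t3tri","birth","w6","w11","w24")`.
#' @param interaction_effects Optional named list outcome -> coefficient
#'   on the product of the true fetal and infant SDS changes.
#' @param missing_rates Named list of availability probabilities; see
#'   defaults in the source.
#' @param covariate_missing Named vector of per-covariate missingness
#'   probabilities (MAR: smoking and folic acid missingness depends on
#'   education).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_children, seed = 1L, tracking_rho = 0.7,
                       effect_map = default_effect_map,
                       covariate_effects = default_covariate_effects,
                       conditional_effects = NULL,
                       interaction_effects = NULL,
                       missing_rates = default_missing_rates,
                       covariate_missing = default_covariate_missing) {
  if (length(n_children) != 1L || is.na(n_children) || n_children < 1)
    stop_eg("n_children must be at least 1")
  if (abs(tracking_rho) >= 1)
    stop_eg("|tracking_rho| must be < 1")
  mr <- utils::modifyList(default_missing_rates, missing_rates)
  probs <- c(unlist(mr), covariate_missing)
  if (any(probs < 0 | probs > 1))
    stop_eg("all availability/missingness probabilities must be in [0, 1]")
  structure(list(
    n_children = as.integer(n_children), seed = as.integer(seed),
    tracking_rho = tracking_rho,
    sd_innovation = sqrt(1 - tracking_rho^2),
    effect_map = effect_map, covariate_effects = covariate_effects,
    conditional_effects = conditional_effects,
    interaction_effects = interaction_effects,
    missing_rates = mr, covariate_missing = covariate_missing,
    # generating infant weight curve: Reed1 per sex, t in years
    reed1_params = list(
      girl = c(A = 7.80652, B = 1.46961, C = 1.78509, D = 0.077116),
      boy = c(A = 7.80652, B = 2.06961, C = 1.78509, D = 0.077116)),
    # generating log BMI cubic, t in months (girls; boys add sex offset)
    logbmi_beta = c(b0 = 2.60505, b1 = 0.06834, b2 = -0.00558,
                    b3 = 0.00012),
    logbmi_sex_boy = 0.02282),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort config: n =", x$n_children, " seed =", x$seed,
      " tracking_rho =", x$tracking_rho, "\n")
  invisible(x)
}

# conditional draw of a bridge point of a stationary AR process given the
# two endpoints, with endpoint-to-mid correlations r_am and r_mb
ar_bridge <- function(z_a, z_b, r_am, r_mb) {
  r_ab <- r_am * r_mb
  mu <- (r_am * (1 - r_mb^2) * z_a + r_mb * (1 - r_am^2) * z_b) /
    (1 - r_ab^2)
  s2 <- (1 - r_am^2) * (1 - r_mb^2) / (1 - r_ab^2)
  mu + sqrt(s2) * stats::rnorm(length(z_a))
}

# mix two probabilities over a binary stratum (prevalence w of the
# "shifted" level, odds ratio or) so the marginal equals p
mar_probs <- function(p, or, w) {
  if (p <= 0 || p >= 1 || or == 1) return(c(p0 = p, p1 = p))
  f <- function(p1) {
    o1 <- p1 / (1 - p1) / or
    p0 <- o1 / (1 + o1)
    w * p1 + (1 - w) * p0 - p
  }
  p1 <- stats::uniroot(f, c(1e-6, 1 - 1e-6))$root
  o1 <- p1 / (1 - p1) / or
  c(p0 = o1 / (1 + o1), p1 = p1)
}

# Hadlock-consistent biometry: reference biometry at gestational age,
# scaled so the Hadlock EFW equals the target weight (vectorized bisection)
biometry_for_efw <- function(ga, efw_g) {
  hc0 <- interp_anchor(ga, c(20, 30.4), c(17.5, 28.5))
  ac0 <- interp_anchor(ga, c(20, 30.4), c(15.0, 26.0))
  fl0 <- interp_anchor(ga, c(20, 30.4), c(3.0, 5.7))
  target <- log10(efw_g)
  lo <- rep(0.3, length(ga)); hi <- rep(2.5, length(ga))
  f <- function(s) {
    hc <- s * hc0; ac <- s * ac0; fl <- s * fl0
    1.326 - 0.00326 * ac * fl + 0.0107 * hc + 0.0438 * ac + 0.158 * fl -
      target
  }
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    up <- f(mid) < 0
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
  }
  s <- (lo + hi) / 2
  list(hc = s * hc0, ac = s * ac0, fl = s * fl0)
}

reed1_w <- function(p, t) p[["A"]] + p[["B"]] * t + p[["C"]] * log(t) +
  p[["D"]] / t

# generating reference curves (shared by the simulator and
# generating_charts): log EFW trend/SD by gestational age, birth-weight
# mean by gestational age and sex, infant weight SD by age in months
eg_efw_mu <- function(ga) log(378) + (log(1622) - log(378)) / 9.8 *
  (ga - 20.6)
eg_efw_sd <- function(ga) 0.2323 + (0.1526 - 0.2323) / 9.8 * (ga - 20.6)
eg_bw_mean <- function(ga, boy) 3444 + 180 * (ga - 40.1) +
  ifelse(boy, 64, -62)
eg_sd_w <- function(m) interp_anchor(m, c(0, 1.05, 3.3, 6.2, 11.1, 25.2),
                                     c(0.48, 0.55, 0.70, 0.88, 1.03, 1.49))

#' Exact reference charts of the generating population
#'
#' Builds `ref_chart` objects directly from the generating curves of
#' [simulate_cohort()] — the synthetic analogue of external population
#' reference charts (such as WHO fetal or national infant charts), whose
#' means and SDs carry no sampling noise from the analysis cohort.
#' Standardizing a simulated cohort against these charts emulates a study
#' that uses external references; [cohort_charts()] is the
#' internal-reference alternative.
#'
#' @param config The [sim_config()] the cohort was generated with.
#' @return Named list of `ref_chart` objects: `efw2`, `efw3`, `birth`,
#'   `w6`, `w11`, `w24`.
#' @export
generating_charts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mk <- function(ages, mu, sd, transform, axis, measure, sexes = FALSE,
                 margin = 2) {
    grid <- if (sexes) {
      do.call(rbind, lapply(c("girl", "boy"), function(s)
        data.frame(sex = s, age = ages, mean = mu(ages, s == "boy"),
                   sd = sd(ages))))
    } else data.frame(sex = "all", age = ages, mean = mu(ages),
                      sd = sd(ages))
    structure(list(measure = measure, axis = axis, transform = transform,
                   sex_specific = sexes, grid = grid, margin = margin,
                   extrapolation = "linear"),
              class = "ref_chart")
  }
  w_mu <- function(m, boy) {
    p <- if (boy) config$reed1_params$boy else config$reed1_params$girl
    reed1_w(p, m / 12)
  }
  list(
    efw2 = mk(seq(18, 24, 0.5), eg_efw_mu, eg_efw_sd, "log",
              "gestational-weeks", "efw2"),
    efw3 = mk(seq(27.5, 33.5, 0.5), eg_efw_mu, eg_efw_sd, "log",
              "gestational-weeks", "efw3"),
    birth = mk(seq(33, 43, 0.5), eg_bw_mean, function(a) rep(480, length(a)),
               "identity", "gestational-weeks", "birth", sexes = TRUE),
    w6 = mk(seq(4.5, 8.25, 0.25), w_mu, eg_sd_w, "identity",
            "postnatal-months", "w6", sexes = TRUE),
    w11 = mk(seq(9.5, 13.25, 0.25), w_mu, eg_sd_w, "identity",
             "postnatal-months", "w11", sexes = TRUE),
    w24 = mk(seq(22.5, 28.5, 0.5), w_mu, eg_sd_w, "identity",
             "postnatal-months", "w24", sexes = TRUE))
}

#' Simulate a synthetic longitudinal growth cohort
#'
#' Generates one child per row with the full wide schema the pipeline
#' reads: fetal ultrasound biometry at ~20 and ~30 weeks (consistent with
#' the Hadlock formula), birth weight and gestational age, infant weights
#' and lengths at ~2 weeks and ~1, ~3, ~6, ~11 and ~24 months, a
#' childhood (~10 y)
#' visit with height, weight, DXA fat and fat-free mass, MRI visceral and
#' pericardial fat volumes and four liver fat-fraction samples, and
#' maternal/child covariates. The latent weight-SDS sequence per child is
#' a stationary first-order autoregressive process with coefficient
#' `tracking_rho` (which reproduces tracking and the regression to the
#' mean that makes infant catch-up growth more common after fetal
#' deceleration); raw measurements are reconstructed from the latent SDS
#' through the generating reference curves. Adiposity outcomes are
#' generated on the natural-log scale with the configured pattern,
#' covariate and (optionally) conditional/interaction effects injected in
#' outcome-SDS units; missingness follows the configured availability
#' rates and is missing-at-random given maternal education. Columns
#' prefixed `true_` record the latent truth (pattern and injected
#' effects) for parameter-recovery studies.
#'
#' @param config A [sim_config()].
#' @return Data frame of class `synthetic_cohort`, one row per child,
#'   with the configuration attached as attribute `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_children
  rho <- config$tracking_rho
  mr <- config$missing_rates

  sex <- factor(ifelse(stats::runif(n) < 0.509, "girl", "boy"),
                levels = c("girl", "boy"))
  boy <- sex == "boy"

  # --- covariates (marginals loosely matching a Dutch birth cohort) ---
  maternal_age <- stats::rnorm(n, 31.1, 4.9)
  education <- factor(ifelse(stats::runif(n) < 0.474, "lower", "higher"),
                      levels = c("higher", "lower"))
  prepreg_bmi <- exp(stats::rnorm(n, log(22.5), 0.163))
  smoking <- factor(ifelse(stats::runif(n) < 0.228, "yes", "no"),
                    levels = c("no", "yes"))
  folic_acid <- factor(ifelse(stats::runif(n) < 0.798, "yes", "no"),
                       levels = c("no", "yes"))
  parity <- factor(ifelse(stats::runif(n) < 0.578, "nulliparous",
                          "multiparous"),
                   levels = c("nulliparous", "multiparous"))
  ethnicity <- factor(ifelse(stats::runif(n) < 0.679, "European",
                             "non-European"),
                      levels = c("European", "non-European"))
  breastfeeding <- factor(ifelse(stats::runif(n) < 0.928, "ever", "never"),
                          levels = c("never", "ever"))
  child_age <- stats::rnorm(n, 9.8, 0.3)

  # --- latent AR(1) weight SDS at 20w, 30w, birth, 6, 11, 24 months ---
  Z <- matrix(NA_real_, n, 6,
              dimnames = list(NULL, c("t2tri", "t3tri", "birth",
                                      "w6", "w11", "w24")))
  Z[, 1] <- stats::rnorm(n)
  innov <- matrix(NA_real_, n, 6)
  innov[, 1] <- Z[, 1]
  for (k in 2:6) {
    e <- stats::rnorm(n)
    innov[, k] <- e
    Z[, k] <- rho * Z[, k - 1] + config$sd_innovation * e
  }
  # bridge latents for the ~2-week, ~1- and ~3-month trajectory visits
  r1 <- rho^(1.05 / 6.2); rrest <- rho / r1
  z_1m <- ar_bridge(Z[, "birth"], Z[, "w6"], r1, rrest)
  z_2w <- ar_bridge(Z[, "birth"], z_1m, rho^(0.5 / 6.2),
                    rho^(0.55 / 6.2))
  r2 <- rho^(3.3 / 6.2) / r1
  r3 <- rho / (r1 * r2)
  z_3m <- ar_bridge(z_1m, Z[, "w6"], r2, r3)

  # --- visit ages ---
  clipn <- function(n, m, s, lo, hi) pmin(pmax(stats::rnorm(n, m, s), lo), hi)
  ga_2tri <- clipn(n, 20.6, 1.1, 18.5, 23)
  ga_3tri <- clipn(n, 30.4, 1.0, 28, 33)
  ga_birth <- clipn(n, 40.1, 1.5, 33, 42.5)
  age_2w <- clipn(n, 0.55, 0.1, 0.5, 0.9)
  age_1m <- clipn(n, 1.05, 0.15, 0.6, 1.6)
  age_3m <- clipn(n, 3.3, 0.35, 2.3, 4.4)
  age_6m <- clipn(n, 6.2, 0.5, 5.0, 7.8)
  age_11m <- clipn(n, 11.1, 0.65, 9.8, 12.8)
  age_24m <- clipn(n, 25.2, 1.1, 23, 28)

  # --- fetal weights (lognormal around a log-linear gestational trend) ---
  efw2 <- exp(eg_efw_mu(ga_2tri) + eg_efw_sd(ga_2tri) * Z[, "t2tri"])
  efw3 <- exp(eg_efw_mu(ga_3tri) + eg_efw_sd(ga_3tri) * Z[, "t3tri"])
  b2 <- biometry_for_efw(ga_2tri, efw2)
  b3 <- biometry_for_efw(ga_3tri, efw3)

  # --- birth weight: linear in gestational age, sex-shifted ---
  birth_weight_g <- eg_bw_mean(ga_birth, boy) + 480 * Z[, "birth"]

  # --- infant weights from the generating Reed1 curves ---
  w_at <- function(m, z) {
    w <- ifelse(boy, reed1_w(config$reed1_params$boy, m / 12),
                reed1_w(config$reed1_params$girl, m / 12))
    w + eg_sd_w(m) * z
  }
  weight_2w <- w_at(age_2w, z_2w)
  weight_1m <- w_at(age_1m, z_1m)
  weight_3m <- w_at(age_3m, z_3m)
  weight_6m <- w_at(age_6m, Z[, "w6"])
  weight_11m <- w_at(age_11m, Z[, "w11"])
  weight_24m <- w_at(age_24m, Z[, "w24"])

  # --- infant lengths, tied to the generating log-BMI cubic ---
  bmi_curve <- function(m) {
    b <- config$logbmi_beta
    exp(b[["b0"]] + ifelse(boy, config$logbmi_sex_boy, 0) +
          b[["b1"]] * m + b[["b2"]] * m^2 + b[["b3"]] * m^3)
  }
  sd_len <- function(m) interp_anchor(m, c(0, 6.2, 11.1, 25.2),
                                      c(2.2, 2.4, 2.5, 2.9))
  len_at <- function(m, z) {
    w_mean <- ifelse(boy, reed1_w(config$reed1_params$boy, m / 12),
                     reed1_w(config$reed1_params$girl, m / 12))
    mu <- 100 * sqrt(w_mean / bmi_curve(m))
    mu + sd_len(m) * (0.6 * z + 0.8 * stats::rnorm(n))
  }
  length_2w <- len_at(age_2w, z_2w)
  length_1m <- len_at(age_1m, z_1m)
  length_3m <- len_at(age_3m, z_3m)
  length_6m <- len_at(age_6m, Z[, "w6"])
  length_11m <- len_at(age_11m, Z[, "w11"])
  length_24m <- len_at(age_24m, Z[, "w24"])

  # --- missingness ---
  w_lower <- mean(education == "lower")
  p24 <- mar_probs(mr$w24, 0.6, w_lower)
  has24 <- stats::runif(n) < ifelse(education == "lower",
                                    p24["p1"], p24["p0"])
  p11 <- mar_probs(mr$w11_given_no24, 0.6, w_lower)
  has11 <- ifelse(has24, stats::runif(n) < mr$w11_with_w24,
                  stats::runif(n) < ifelse(education == "lower",
                                           p11["p1"], p11["p0"]))
  has6 <- ifelse(has24 | has11, stats::runif(n) < mr$w6_with_later,
                 stats::runif(n) < mr$w6_given_neither)
  has_fetal_full <- stats::runif(n) < mr$fetal_full
  drop3 <- !has_fetal_full & stats::runif(n) < 0.5
  has2tri <- has_fetal_full | !drop3
  has3tri <- has_fetal_full | drop3
  has2w <- stats::runif(n) < mr$early_visits
  has1m <- stats::runif(n) < mr$early_visits
  has3mv <- stats::runif(n) < mr$early_visits

  # --- true growth pattern (with the 24->11->6 month fallback) ---
  z_sel <- ifelse(has24, Z[, "w24"], ifelse(has11, Z[, "w11"],
                                            ifelse(has6, Z[, "w6"], NA)))
  src_sel <- ifelse(has24, "24mo", ifelse(has11, "11mo",
                                          ifelse(has6, "6mo", NA)))
  fetal_delta_true <- ifelse(has2tri, Z[, "birth"] - Z[, "t2tri"], NA)
  infant_delta_true <- z_sel - Z[, "birth"]
  fcat <- classify_change(fetal_delta_true)
  icat <- classify_change(infant_delta_true)
  true_pattern <- combined_pattern(fcat, icat)

  # --- injected outcome effects, outcome-SDS units ---
  outcomes <- c("fmi", "ffmi", "visceral", "liver", "pericardial")
  eff <- matrix(0, n, length(outcomes),
                dimnames = list(NULL, outcomes))
  for (oc in outcomes) {
    em <- config$effect_map[[oc]]
    if (!is.null(em)) {
      e <- em[as.character(true_pattern)]
      eff[, oc] <- eff[, oc] + ifelse(is.na(e), 0, e)
    }
    ce <- config$covariate_effects
    if (!is.null(ce$smoking))
      eff[, oc] <- eff[, oc] + ce$smoking * (smoking == "yes")
    if (!is.null(ce$prepreg_bmi))
      eff[, oc] <- eff[, oc] +
        ce$prepreg_bmi * (log(prepreg_bmi) - log(22.5)) / 0.163
    if (!is.null(ce$education))
      eff[, oc] <- eff[, oc] + ce$education * (education == "lower")
    if (!is.null(ce$breastfeeding))
      eff[, oc] <- eff[, oc] + ce$breastfeeding * (breastfeeding == "ever")
    nde <- config$conditional_effects[[oc]]
    if (!is.null(nde))
      for (tp in names(nde))
        eff[, oc] <- eff[, oc] + nde[[tp]] * innov[, match(tp, colnames(Z))]
    ie <- config$interaction_effects[[oc]]
    if (!is.null(ie)) {
      prod_term <- fetal_delta_true * infant_delta_true
      eff[, oc] <- eff[, oc] + ie * ifelse(is.na(prod_term), 0, prod_term)
    }
  }

  # --- childhood visit ---
  height_cm <- 141.7 + 6.7 * (0.35 * Z[, "w24"] +
                                sqrt(1 - 0.35^2) * stats::rnorm(n))
  h_m <- height_cm / 100
  sig <- c(fmi = 0.3636, ffmi = 0.084, visceral = 0.4626,
           liver = 0.349, pericardial = 0.408)
  fat_mass_kg <- exp(log(2.1) + 4 * log(h_m) +
                       sig[["fmi"]] * (eff[, "fmi"] + stats::rnorm(n)))
  fat_free_mass_kg <- exp(log(12.5) + 2 * log(h_m) +
                            sig[["ffmi"]] * (eff[, "ffmi"] +
                                               stats::rnorm(n)))
  child_weight_kg <- fat_mass_kg + fat_free_mass_kg +
    abs(stats::rnorm(n, 0.4, 0.15))
  visceral_g <- exp(log(358) + 3 * (log(h_m) - log(1.417)) +
                      sig[["visceral"]] * (eff[, "visceral"] +
                                             stats::rnorm(n)))
  pericardial_g <- exp(log(10.6) + 3 * (log(h_m) - log(1.417)) +
                         sig[["pericardial"]] * (eff[, "pericardial"] +
                                                   stats::rnorm(n)))
  liver_pct <- exp(log(2.0) + sig[["liver"]] * (eff[, "liver"] +
                                                  stats::rnorm(n)))
  liver_s <- vapply(1:4, function(j)
    pmax(liver_pct + stats::rnorm(n, 0, 0.08), 0.1), numeric(n))

  has_dxa <- stats::runif(n) < mr$dxa
  has_visc <- stats::runif(n) < mr$visceral
  has_liver <- stats::runif(n) < mr$liver
  has_peri <- stats::runif(n) < mr$pericardial

  na_if <- function(x, keep) replace(x, !keep, NA)
  cohort <- data.frame(
    id = seq_len(n), sex = sex, child_age = child_age,
    maternal_age = maternal_age, education = education,
    prepreg_bmi = prepreg_bmi, smoking = smoking,
    folic_acid = folic_acid, parity = parity, ethnicity = ethnicity,
    breastfeeding = breastfeeding,
    ga_2tri = na_if(ga_2tri, has2tri),
    hc_2tri = na_if(b2$hc, has2tri), ac_2tri = na_if(b2$ac, has2tri),
    fl_2tri = na_if(b2$fl, has2tri),
    ga_3tri = na_if(ga_3tri, has3tri),
    hc_3tri = na_if(b3$hc, has3tri), ac_3tri = na_if(b3$ac, has3tri),
    fl_3tri = na_if(b3$fl, has3tri),
    ga_birth = ga_birth, birth_weight_g = birth_weight_g,
    age_2w = na_if(age_2w, has2w), weight_2w = na_if(weight_2w, has2w),
    length_2w = na_if(length_2w, has2w),
    age_1m = na_if(age_1m, has1m), weight_1m = na_if(weight_1m, has1m),
    length_1m = na_if(length_1m, has1m),
    age_3m = na_if(age_3m, has3mv), weight_3m = na_if(weight_3m, has3mv),
    length_3m = na_if(length_3m, has3mv),
    age_6m = na_if(age_6m, has6), weight_6m = na_if(weight_6m, has6),
    length_6m = na_if(length_6m, has6),
    age_11m = na_if(age_11m, has11), weight_11m = na_if(weight_11m, has11),
    length_11m = na_if(length_11m, has11),
    age_24m = na_if(age_24m, has24), weight_24m = na_if(weight_24m, has24),
    length_24m = na_if(length_24m, has24),
    child_height_cm = height_cm, child_weight_kg = child_weight_kg,
    fat_mass_kg = na_if(fat_mass_kg, has_dxa),
    fat_free_mass_kg = na_if(fat_free_mass_kg, has_dxa),
    visceral_fat_vol_ml = na_if(visceral_g / 0.9, has_visc),
    pericardial_fat_vol_ml = na_if(pericardial_g / 0.9, has_peri),
    liver_fat_s1 = na_if(liver_s[, 1], has_liver),
    liver_fat_s2 = na_if(liver_s[, 2], has_liver),
    liver_fat_s3 = na_if(liver_s[, 3], has_liver),
    liver_fat_s4 = na_if(liver_s[, 4], has_liver),
    true_pattern = as.character(true_pattern),
    true_fetal_delta = fetal_delta_true,
    true_infant_delta = infant_delta_true,
    true_infant_source = src_sel,
    stringsAsFactors = FALSE)

  # MAR covariate missingness: lifestyle covariates are more often
  # missing for lower-educated mothers; education itself is MCAR
  cm <- config$covariate_missing
  ed_dep <- c("smoking", "folic_acid", "breastfeeding", "prepreg_bmi")
  for (v in names(cm)) {
    if (cm[[v]] <= 0) next
    if (v %in% ed_dep) {
      pv <- mar_probs(cm[[v]], 1.5, w_lower)
      p <- ifelse(education == "lower", pv["p1"], pv["p0"])
    } else p <- cm[[v]]
    cohort[[v]][stats::runif(n) < p] <- NA
  }

  attr(cohort, "config") <- config
  class(cohort) <- c("synthetic_cohort", class(cohort))
  cohort
}

#' Write / read a cohort as delimited text
#'
#' One row per child, comma-separated, missing values as empty fields.
#' `write_cohort` then `read_cohort` round-trips all values.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
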