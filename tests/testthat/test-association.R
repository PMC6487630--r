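make_assoc_data <- function(n = 300, effect = 0.3, seed = 51) {
  set.seed(seed)
  x <- rnorm(n)
  data.frame(
    y = effect * x + rnorm(n),
    x = x,
    child_age = rnorm(n, 9.8, 0.3),
    sex = factor(sample(c("girl", "boy"), n, TRUE)))
}

test_that("association models report t-based confidence intervals", {
  d <- make_assoc_data(400, effect = 0.3)
  r <- fit_association(d, "y", "x", covariates = c("child_age", "sex"))
  f <- lm(y ~ x + child_age + sex, data = d)
  expect_equal(r$estimate, unname(coef(f)["x"]), tolerance = 1e-12)
  ci <- confint(f)["x", ]
  expect_equal(c(r$ci_low, r$ci_high), unname(ci), tolerance = 1e-10)
  expect_true(r$ci_low < r$estimate && r$estimate < r$ci_high)
  expect_equal(r$n, 400L)
})

test_that("constant or aliased exposures raise a rank error", {
  d <- make_assoc_data(100)
  d$x <- 1
  expect_error(fit_association(d, "y", "x",
                               covariates = c("child_age", "sex")),
               "rank-deficient")
})

test_that("factor exposures yield one contrast per non-reference level", {
  set.seed(52)
  n <- 450
  g <- factor(sample(c("normal/normal", "deceleration/acceleration",
                       "acceleration/normal"), n, TRUE),
              levels = c("normal/normal", "deceleration/acceleration",
                         "acceleration/normal"))
  d <- data.frame(y = 0.4 * (g == "deceleration/acceleration") + rnorm(n),
                  pattern = g, child_age = rnorm(n, 9.8, 0.3),
                  sex = factor(sample(c("girl", "boy"), n, TRUE)))
  r <- fit_association(d, "y", "pattern", covariates = c("child_age", "sex"))
  expect_equal(nrow(r), 2L)
  hit <- r[grepl("deceleration/acceleration", r$level), ]
  expect_true(hit$ci_low < 0.4 && 0.4 < hit$ci_high)
})

test_that("interaction test is calibrated and powered", {
  set.seed(53)
  n <- 2500
  f <- rnorm(n); i <- rnorm(n)
  d <- data.frame(fetal_delta = f, infant_delta = i,
                  y = 0.2 * f * i + rnorm(n),
                  child_age = rnorm(n, 9.8, 0.3),
                  sex = factor(sample(c("girl", "boy"), n, TRUE)))
  expect_lt(interaction_test(d, "y"), 0.05)
  d$y <- rnorm(n)
  p <- interaction_test(d, "y")
  expect_true(p > 0 && p <= 1)
  d$infant_delta <- NA_real_
  expect_error(interaction_test(d, "y"), "complete rows")
})

test_that("stratified models recover a known growth-measure effect", {
  set.seed(54)
  n <- 900
  d <- data.frame(
    birth_size = factor(rep(c("AGA", "SGA"), c(n - 12, 12)),
                        levels = c("SGA", "AGA", "LGA")),
    bmiap = rnorm(n, 17.6, 0.8),
    child_age = rnorm(n, 9.8, 0.3),
    sex = factor(sample(c("girl", "boy"), n, TRUE)),
    birth_weight_g = rnorm(n, 3444, 554))
  d$y <- 0.19 * (d$bmiap - 17.6) / 0.8 + rnorm(n)
  d$bmiap_sds <- (d$bmiap - mean(d$bmiap)) / sd(d$bmiap)
  r <- stratified_infant_models(
    d, outcomes = "y", exposures = "bmiap_sds",
    covariates = c("child_age", "sex", "birth_weight_g"))
  aga <- r[r$stratum == "AGA", ]
  expect_false(aga$skipped)
  expect_true(aga$ci_low < 0.19 && 0.19 < aga$ci_high)
  sga <- r[r$stratum == "SGA", ]
  expect_true(sga$skipped)
  expect_true(is.na(sga$estimate))
})

test_that("Rubin pooling reduces to the single fit when imputations agree", {
  r1 <- data.frame(outcome = "y", exposure = "x", level = "x",
                   stratum = "all", model = "main", estimate = 0.10,
                   se = 0.05, ci_low = NA, ci_high = NA, p = NA,
                   n = 100L, df = 96, pooled = FALSE)
  pooled <- pool_rubin(rbind(r1, r1, r1))
  expect_equal(pooled$estimate, 0.10)
  expect_equal(pooled$se, 0.05, tolerance = 1e-12)
  expect_equal(pooled$df, 96)
  expect_equal(pool_rubin(r1)$se, 0.05)  # m = 1 is the identity
})

test_that("Rubin pooling matches the hand-computed 3-imputation example", {
  rs <- do.call(rbind, lapply(c(0.1, 0.2, 0.3), function(e)
    data.frame(outcome = "y", exposure = "x", level = "x", stratum = "all",
               model = "main", estimate = e, se = 0.05, ci_low = NA,
               ci_high = NA, p = NA, n = 100L, df = 96, pooled = FALSE)))
  pooled <- pool_rubin(rs)
  # by hand: qbar 0.2; ubar 0.0025; b 0.01; T = 0.0025 + (4/3)*0.01
  expect_equal(pooled$estimate, 0.2, tolerance = 1e-12)
  expect_equal(pooled$se^2, 0.0025 + (1 + 1 / 3) * 0.01, tolerance = 1e-12)
  expect_equal(pooled$se, sqrt(0.01583333333333333), tolerance = 1e-12)
  # pooled SE is never below the mean within-imputation SE
  expect_gte(pooled$se, 0.05)
})

test_that("imputation of complete covariates returns identical copies", {
  d <- make_assoc_data(120)
  imps <- impute_covariates(d, c("child_age", "sex"), m = 3, seed = 9)
  expect_length(imps, 3L)
  expect_identical(imps[[1]], imps[[2]])
  expect_identical(imps[[1]]$child_age, d$child_age)
  # and pooling equals the complete-data fit exactly
  pooled <- pooled_association(imps, outcome = "y", exposure = "x",
                               covariates = c("child_age", "sex"))
  single <- fit_association(d, "y", "x", covariates = c("child_age", "sex"))
  expect_equal(pooled$estimate, single$estimate, tolerance = 1e-12)
  expect_equal(pooled$se, single$se, tolerance = 1e-12)
})

test_that("chained imputation recovers a known MAR conditional mean", {
  # x2 = 1 + 2 x1 + noise, missing where x1 is high (MAR given x1)
  devs <- replicate(8, {
    n <- 600
    x1 <- rnorm(n)
    x2 <- 1 + 2 * x1 + rnorm(n)
    d <- data.frame(x1 = x1, x2 = x2)
    drop <- runif(n) < plogis(-1 + 1.5 * x1)
    d$x2[drop] <- NA
    truth <- mean(1 + 2 * x1[drop])
    imps <- impute_covariates(d, c("x1", "x2"), m = 5,
                              seed = sample.int(1e6, 1))
    imp_mean <- mean(vapply(imps, function(dd) mean(dd$x2[drop]),
                            numeric(1)))
    imp_mean - truth
  })
  expect_lt(abs(mean(devs)), 2 * sd(devs) / sqrt(length(devs)) + 0.05)
})

test_that("covariates with no observed values are rejected", {
  d <- data.frame(a = rnorm(10), b = NA_real_)
  expect_error(impute_covariates(d, c("a", "b")), "no observed values")
  d2 <- data.frame(a = rnorm(100), b = c(rnorm(20), rep(NA, 80)))
  expect_error(impute_covariates(d2, c("a", "b"), max_missing = 0.6),
               "max_missing")
})
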