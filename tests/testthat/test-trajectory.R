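reed1_curve <- function(A, B, C, D, t) A + B * t + C * log(t) + D / t

test_that("noiseless Reed1 data are recovered exactly", {
  t <- c(0.05, 0.1, 0.25, 0.5, 1, 2)
  d <- data.frame(child = 1, sex = "girl", age = t,
                  weight = reed1_curve(3, 10, 4, 1, t))
  fit <- fit_reed1(d, method = "ols")
  expect_equal(unname(fit$fixed$girl), c(3, 10, 4, 1), tolerance = 1e-6)
})

test_that("observations at or before birth are rejected", {
  d <- data.frame(child = 1, sex = "girl", age = c(0, 0.5, 1, 1.5),
                  weight = c(3, 7, 9, 11))
  expect_error(fit_reed1(d), "2 weeks")
  expect_error(fit_reed1(data.frame(child = 1:8, sex = "girl", age = 0.5,
                                    weight = 8)), "distinct ages")
})

test_that("closed-form peak weight velocity matches the velocity curve", {
  d <- data.frame(child = 1, sex = "girl",
                  age = c(0.05, 0.1, 0.25, 0.5, 1, 2),
                  weight = reed1_curve(3, 10, 4, 1,
                                       c(0.05, 0.1, 0.25, 0.5, 1, 2)))
  fit <- fit_reed1(d, method = "ols")
  pk <- peak_weight_velocity(fit)
  # interior maximum of v(t) = B + C/t - D/t^2 at t = 2D/C
  expect_equal(pk$t_peak, 0.5, tolerance = 1e-6)
  expect_equal(pk$pwv, 14, tolerance = 1e-6)  # B + C^2/(4D)
  expect_true(pk$interior)
  # grid-search oracle
  tt <- seq(0.04, 2, by = 1e-4)
  v <- 10 + 4 / tt - 1 / tt^2
  expect_equal(pk$pwv, max(v), tolerance = 1e-3)
  expect_equal(pk$t_peak, tt[which.max(v)], tolerance = 1e-3)
})

test_that("non-interior velocity peaks are flagged", {
  # C <= 0: velocity has no interior maximum
  t <- c(0.1, 0.3, 0.6, 1, 1.5, 2)
  d <- data.frame(child = 1, sex = "girl", age = t,
                  weight = reed1_curve(5, 8, -1, 0.5, t))
  pk <- peak_weight_velocity(fit_reed1(d, method = "ols"))
  expect_false(pk$interior)
  expect_true(is.finite(pk$pwv))
  # degenerate C, D: velocity is essentially constant B
  d2 <- data.frame(child = 1, sex = "girl", age = t,
                   weight = reed1_curve(4, 12, 1e-4, 1e-4, t))
  pk2 <- peak_weight_velocity(fit_reed1(d2, method = "ols"))
  expect_equal(pk2$pwv, 12, tolerance = 1e-2)
})

test_that("mixed Reed1 fit recovers fixed effects from noisy data", {
  set.seed(31)
  nkid <- 150
  obs <- do.call(rbind, lapply(seq_len(nkid), function(i) {
    t <- sort(runif(8, 0.05, 2))
    a_i <- rnorm(1, 0, 0.3)
    data.frame(child = i, sex = "girl", age = t,
               weight = reed1_curve(3 + a_i, 10, 4, 1, t) +
                 rnorm(8, 0, 0.1))
  }))
  fit <- fit_reed1(obs, method = "mixed")
  expect_equal(unname(fit$fixed$girl), c(3, 10, 4, 1), tolerance = 0.05)
  pk <- peak_weight_velocity(fit)
  expect_equal(mean(pk$pwv), 14, tolerance = 0.05)
})

test_that("noiseless cubic log-BMI data are recovered exactly", {
  ages <- c(1, 3, 6, 9, 12, 15)
  beta <- c(2.833, 0.0576, -0.0048, 0.0001)
  d <- data.frame(child = 1, sex = "girl", age = ages,
                  bmi = exp(beta[1] + beta[2] * ages + beta[3] * ages^2 +
                              beta[4] * ages^3))
  fit <- fit_logbmi_cubic(d, method = "ols")
  expect_equal(unname(fit$beta), beta, tolerance = 1e-8)
})

test_that("adiposity peak solves the derivative quadratic by hand", {
  # 3*0.0001 t^2 - 0.0096 t + 0.0576 = 0 -> t in {8, 24}; the second
  # derivative at t = 8 is negative, and 24 is outside the window
  ages <- c(1, 3, 6, 9, 12, 15)
  beta <- c(2.833, 0.0576, -0.0048, 0.0001)
  d <- data.frame(child = 1, sex = "girl", age = ages,
                  bmi = exp(beta[1] + beta[2] * ages + beta[3] * ages^2 +
                              beta[4] * ages^3))
  pk <- adiposity_peak(fit_logbmi_cubic(d, method = "ols"))
  expect_equal(pk$ageap, 8, tolerance = 1e-6)
  expect_equal(pk$bmiap, exp(3.0378), tolerance = 1e-3)
  expect_true(pk$interior)
})

test_that("quadratic limit and degenerate curves behave as contracts say", {
  ages <- c(1, 4, 8, 12, 16)
  # beta3 = 0: vertex at -b1/(2 b2)
  b <- c(2.8, 0.04, -0.0025, 0)
  d <- data.frame(child = 1, sex = "girl", age = ages,
                  bmi = exp(b[1] + b[2] * ages + b[3] * ages^2))
  pk <- adiposity_peak(fit_logbmi_cubic(d, method = "ols"))
  expect_equal(pk$ageap, -0.04 / (2 * -0.0025), tolerance = 1e-6)
  # flat curve: no peak
  d2 <- data.frame(child = 1, sex = "girl", age = ages, bmi = 17)
  pk2 <- adiposity_peak(fit_logbmi_cubic(d2, method = "ols"))
  expect_true(is.na(pk2$ageap))
  expect_false(pk2$interior)
})

test_that("cubic mixed model recovers fixed effects from noisy data", {
  set.seed(32)
  nkid <- 150
  beta <- c(2.61, 0.068, -0.0056, 0.00012)
  obs <- do.call(rbind, lapply(seq_len(nkid), function(i) {
    t <- sort(runif(5, 0.5, 17))
    u <- rnorm(1, 0, 0.04)
    data.frame(child = i, sex = "girl", age = t,
               bmi = exp(beta[1] + u + beta[2] * t + beta[3] * t^2 +
                           beta[4] * t^3 + rnorm(5, 0, 0.03)))
  }))
  fit <- fit_logbmi_cubic(obs, method = "mixed")
  expect_lt(abs(unname(fit$beta[1]) - beta[1]), 0.02)
  expect_lt(abs(unname(fit$beta[2]) - beta[2]), 0.005)
})

test_that("cohort trajectories reproduce the generating PWV and peak", {
  pwvs <- ageaps <- bmiaps <- numeric(3)
  for (i in 1:3) {
    cfg <- sim_config(1500, seed = 200 + i)
    co <- simulate_cohort(cfg)
    long <- cohort_long_weights(co)
    fit <- fit_reed1(long[, c("child", "sex", "age", "weight")])
    pwvs[i] <- mean(peak_weight_velocity(fit)$pwv, na.rm = TRUE)
    cub <- fit_logbmi_cubic(data.frame(child = long$child, sex = long$sex,
                                       age = long$age_months,
                                       bmi = long$bmi))
    pk <- adiposity_peak(cub)
    ageaps[i] <- mean(pk$ageap, na.rm = TRUE)
    bmiaps[i] <- mean(pk$bmiap, na.rm = TRUE)
  }
  # generating values: PWV 12.1 kg/y (sex mix of B +/- 0.3), peak at
  # 8.4 months, BMI ~17.6 at peak
  expect_equal(mean(pwvs), 12.1, tolerance = 0.3 / 12.1)
  expect_equal(mean(ageaps), 8.4, tolerance = 0.1)
  expect_equal(mean(bmiaps), 17.6, tolerance = 0.02)
})
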