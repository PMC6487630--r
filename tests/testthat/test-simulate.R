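test_that("invalid configurations are rejected", {
  expect_error(sim_config(0), "at least 1")
  expect_error(sim_config(10, tracking_rho = 1), "tracking_rho")
  expect_error(sim_config(10, tracking_rho = -1.2), "tracking_rho")
  expect_error(sim_config(10, missing_rates = list(w24 = 1.4)), "\\[0, 1\\]")
})

test_that("a fixed seed reproduces the cohort exactly", {
  a <- quick_cohort(200, seed = 77)
  b <- quick_cohort(200, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- quick_cohort(200, seed = 78)
  expect_false(identical(a$birth_weight_g, c2$birth_weight_g))
})

test_that("latent weight SDS track with the configured correlation", {
  co <- quick_cohort(1500, seed = 5, tracking_rho = 0.7)
  sm <- true_sds(co)
  ok <- complete.cases(sm$birth_sds, sm$w6_sds)
  # AR(1) theory: consecutive SDS correlate at rho
  expect_equal(cor(sm$birth_sds[ok], sm$w6_sds[ok]), 0.7,
               tolerance = 0.05 / 0.7)
  # SDS are marginally standard at each occasion
  for (cn in c("birth_sds", "w6_sds", "w24_sds")) {
    expect_lt(abs(mean(sm[[cn]], na.rm = TRUE)), 0.1)
    expect_equal(sd(sm[[cn]], na.rm = TRUE), 1, tolerance = 0.08)
  }
})

test_that("with no tracking the centile-crossing rate matches theory", {
  co <- quick_cohort(2000, seed = 6, tracking_rho = 0)
  sm <- true_sds(co)
  inf <- select_infant_weight(sm$w24_sds, sm$w11_sds, sm$w6_sds)
  dl <- delta_sds(sm$birth_sds, inf$sds)
  # brute-force bivariate-normal oracle for P(Z2 - Z1 > 0.67), rho = 0
  set.seed(99)
  mc <- mean(rnorm(1e6) - rnorm(1e6) > 0.67)
  obs <- mean(dl > 0.67, na.rm = TRUE)
  n_obs <- sum(!is.na(dl))
  expect_lt(abs(obs - mc), 3 * sqrt(mc * (1 - mc) / n_obs) + 0.01)
})

test_that("availability of infant weights matches the configured rates", {
  co <- quick_cohort(4000, seed = 8)
  mr <- attr(co, "config")$missing_rates
  tol <- function(p, n) 3 * sqrt(p * (1 - p) / n) + 0.01
  p24 <- mean(!is.na(co$weight_24m))
  expect_lt(abs(p24 - mr$w24), tol(mr$w24, 4000))
  no24 <- is.na(co$weight_24m)
  p11 <- mean(!is.na(co$weight_11m[no24]))
  expect_lt(abs(p11 - mr$w11_given_no24), tol(mr$w11_given_no24, sum(no24)))
  neither <- no24 & is.na(co$weight_11m)
  p6 <- mean(!is.na(co$weight_6m[neither]))
  expect_lt(abs(p6 - mr$w6_given_neither),
            tol(mr$w6_given_neither, sum(neither)))
  pf <- mean(!is.na(co$ga_2tri) & !is.na(co$ga_3tri))
  expect_lt(abs(pf - mr$fetal_full), tol(mr$fetal_full, 4000))
})

test_that("lifestyle covariate missingness depends on education (MAR)", {
  co <- quick_cohort(6000, seed = 9)
  miss_lo <- mean(is.na(co$folic_acid[co$education == "lower"]), na.rm = TRUE)
  miss_hi <- mean(is.na(co$folic_acid[co$education == "higher"]), na.rm = TRUE)
  expect_gt(miss_lo, miss_hi)
})

test_that("true pattern labels agree with the recorded latent deltas", {
  co <- quick_cohort(800, seed = 10)
  recomputed <- combined_pattern(classify_change(co$true_fetal_delta),
                                 classify_change(co$true_infant_delta))
  has <- !is.na(co$true_pattern)
  expect_equal(as.character(recomputed[has]), co$true_pattern[has])
})

test_that("cohorts round-trip through delimited text", {
  co <- quick_cohort(150, seed = 12)
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 150L)
  for (cn in names(co)) {
    if (is.numeric(co[[cn]]))
      expect_equal(back[[cn]], co[[cn]], tolerance = 1e-12, label = cn)
    else
      expect_equal(as.character(back[[cn]]), as.character(co[[cn]]),
                   label = cn)
  }
  # missing values are written as empty fields and read back as missing
  expect_identical(is.na(back$weight_24m), is.na(co$weight_24m))
})
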