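test_that("fitted chart recovers a known linear age trend", {
  set.seed(11)
  n <- 3000
  age <- runif(n, 36, 43)
  value <- 3000 + 100 * age + rnorm(n, 0, 400)
  ch <- fit_reference(age, value, n_bins = 4, min_per_bin = 100,
                      axis = "gestational-weeks")
  g <- ch$grid
  # per-bin mean within 2 SE of the generating line
  se <- 400 / sqrt(n / 4)
  expect_true(all(abs(g$mean - (3000 + 100 * g$age)) < 2.5 * se))
  expect_true(all(abs(g$sd - 400) / 400 < 0.15))
})

test_that("degenerate reference samples are rejected", {
  expect_error(fit_reference(c(1, 2, 3), c(5, 5, 5), min_per_bin = 1),
               "zero or undefined SD")
  expect_error(fit_reference(1, 5), "at least 2")
  expect_error(fit_reference(rep(2, 30), rnorm(30), min_per_bin = 50),
               "at least 2")
})

test_that("a single-bin chart works at its age and errors far away", {
  set.seed(2)
  ch <- fit_reference(rnorm(100, 10, 0.1), rnorm(100, 50, 5),
                      n_bins = 1, min_per_bin = 50, margin = 1)
  expect_equal(nrow(ch$grid), 1L)
  expect_true(is.finite(sds(55, 10, ch)))
  expect_error(sds(55, 15, ch), "outside chart range")
})

test_that("SDS is (transformed value - mean) / SD with linear interpolation", {
  ch <- structure(list(measure = "m", axis = "postnatal-months",
                       transform = "identity", sex_specific = FALSE,
                       grid = data.frame(sex = "all", age = c(10, 12),
                                         mean = c(3000, 3200),
                                         sd = c(400, 400)),
                       margin = 1, extrapolation = "linear"),
                  class = "ref_chart")
  expect_equal(sds(3000, 10, ch), 0)
  expect_equal(sds(3400, 10, ch), 1)
  expect_equal(sds(3100, 11, ch), 0)  # midway: interpolated mean 3100
  expect_true(is.na(sds(NA, 11, ch)))
  expect_error(sds(3000, 20, ch), "outside chart range")
})

test_that("linear extrapolation continues the outer segment within margin", {
  ch <- structure(list(measure = "m", axis = "postnatal-months",
                       transform = "identity", sex_specific = FALSE,
                       grid = data.frame(sex = "all", age = c(10, 12),
                                         mean = c(3000, 3200),
                                         sd = c(400, 400)),
                       margin = 2, extrapolation = "linear"),
                  class = "ref_chart")
  expect_equal(sds(3300, 13, ch), 0)  # 3200 + 100*(13-12)
  expect_equal(sds(2900, 9, ch), 0)
})

test_that("SDS of the reference sample itself is calibrated per bin", {
  set.seed(7)
  n <- 4000
  age <- runif(n, 5, 8)
  value <- exp(rnorm(n, 2 + 0.1 * age, 0.3))
  ch <- fit_reference(age, value, transform = "log", n_bins = 4,
                      min_per_bin = 200)
  z <- sds(value, age, ch)
  bins <- cut(age, quantile(age, seq(0, 1, 0.25)), include.lowest = TRUE)
  for (b in levels(bins)) {
    zb <- z[bins == b]
    expect_lt(abs(mean(zb)), 0.05)
    expect_true(sd(zb) > 0.95 && sd(zb) < 1.05)
  }
})

test_that("birth size classes follow the 5th/95th percentile cutoffs", {
  expect_equal(as.character(classify_birth_size(-2)), "SGA")
  expect_equal(as.character(classify_birth_size(0)), "AGA")
  expect_equal(as.character(classify_birth_size(2)), "LGA")
  # qnorm(0.95) = 1.6449: boundary is strict, so exactly on it is AGA
  expect_equal(as.character(classify_birth_size(qnorm(0.95))), "AGA")
  expect_equal(as.character(classify_birth_size(qnorm(0.05))), "AGA")
  expect_true(is.na(classify_birth_size(NA)))
  set.seed(3)
  cls <- classify_birth_size(rnorm(20000))
  expect_equal(mean(cls == "SGA"), 0.05, tolerance = 0.15)
  expect_equal(mean(cls == "LGA"), 0.05, tolerance = 0.15)
  # empirical mode puts exactly the tail fractions outside the cutoffs
  cls_e <- classify_birth_size(rnorm(1000), empirical = TRUE)
  expect_equal(mean(cls_e == "SGA"), 0.05, tolerance = 0.2)
})

test_that("charts round-trip through delimited text", {
  set.seed(5)
  ch <- fit_reference(runif(300, 5, 8), rnorm(300, 8, 1),
                      sex = sample(c("girl", "boy"), 300, TRUE),
                      n_bins = 2, min_per_bin = 30)
  path <- tempfile(fileext = ".csv")
  write_chart(ch, path)
  ch2 <- read_chart(path)
  expect_equal(ch2$grid$mean, ch$grid$mean)
  expect_equal(ch2$grid$sd, ch$grid$sd)
  expect_equal(ch2$transform, ch$transform)
  expect_equal(sds(8.5, 6, ch2, sex = "girl"), sds(8.5, 6, ch, sex = "girl"))
})
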