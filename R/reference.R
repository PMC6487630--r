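#' Build an age- and sex-specific reference chart from a reference sample
#'
#' Constructs an internal reference chart for one measurement: the sample
#' is split into age bins (quantile-based, optionally within sex), the
#' mean and SD of the (optionally log-transformed) measure are computed
#' per bin, and the chart interpolates linearly between bin-centre ages.
#' This stands in for external growth references: all standard deviation
#' scores in the package are relative to a designated reference sample.
#'
#' @param age Numeric vector of ages (gestational weeks or postnatal
#'   months; record which in `axis`).
#' @param value Measurements, same length as `age`.
#' @param sex Optional factor/character (`"girl"`/`"boy"`); when supplied
#'   the chart is fitted per sex.
#' @param transform `"identity"` or `"log"` (natural log of the measure
#'   before locating and scaling).
#' @param n_bins Number of age bins (per sex). With a linear age trend two
#'   bins already identify the line; more bins track curvature at the cost
#'   of per-bin precision.
#' @param min_per_bin Minimum observations per bin; violations error,
#'   naming the bin.
#' @param axis Axis label, `"gestational-weeks"` or `"postnatal-months"`.
#' @param measure Name of the measure (bookkeeping only).
#' @param margin Extrapolation margin beyond the outermost bin-centre
#'   ages, in axis units; queries further out error.
#' @param extrapolation Within the margin, `"linear"` (default) continues
#'   the slope of the outermost grid segment — exact when the underlying
#'   age trend is linear — while `"constant"` holds the edge value.
#' @return An object of class `ref_chart`.
#' @export
fit_reference <- function(age, value, sex = NULL,
                          transform = c("identity", "log"),
                          n_bins = 3L, min_per_bin = 50L,
                          axis = "postnatal-months",
                          measure = "measure", margin = 1,
                          extrapolation = c("linear", "constant")) {
  transform <- match.arg(transform)
  extrapolation <- match.arg(extrapolation)
  ok <- !is.na(age) & !is.na(value) & (is.null(sex) | !is.na(sex %||% TRUE))
  if (!is.null(sex)) ok <- ok & !is.na(sex)
  age <- age[ok]; value <- value[ok]
  if (!is.null(sex)) sex <- as.character(sex)[ok]
  if (length(age) < 2L || length(unique(age)) < 2L)
    stop_eg("need at least 2 observations at distinct ages")
  if (transform == "log") {
    if (any(value <= 0)) stop_eg("log transform requires positive values")
    value <- log(value)
  }
  groups <- if (is.null(sex)) list(all = seq_along(age)) else
    split(seq_along(age), sex)
  grid <- do.call(rbind, lapply(names(groups), function(s) {
    idx <- groups[[s]]
    a <- age[idx]; v <- value[idx]
    nb <- max(1L, min(n_bins, floor(length(a) / min_per_bin)))
    if (nb < 1L || length(a) < min_per_bin)
      stop_eg("insufficient data for sex '", s, "': ", length(a),
              " < min_per_bin = ", min_per_bin)
    br <- unique(stats::quantile(a, probs = seq(0, 1, length.out = nb + 1)))
    bin <- if (length(br) > 2L)
      cut(a, br, include.lowest = TRUE) else factor(rep(1L, length(a)))
    ns <- table(bin)
    if (any(ns < min_per_bin))
      stop_eg("bin ", names(ns)[which.min(ns)], " for sex '", s,
              "' has ", min(ns), " observations (< ", min_per_bin, ")")
    mu <- as.numeric(tapply(v, bin, mean))
    centre <- as.numeric(tapply(a, bin, mean))
    # SD of residuals around the interpolated mean curve, so that a
    # within-bin age trend does not inflate the scale
    resid <- v - if (length(centre) > 1L)
      interp_chart(centre, mu, a, "linear") else mu
    sdv <- as.numeric(tapply(resid, bin, stats::sd))
    if (any(sdv <= 0 | !is.finite(sdv)))
      stop_eg("zero or undefined SD in an age bin for sex '", s, "'")
    data.frame(sex = s, age = centre, mean = mu, sd = sdv)
  }))
  grid <- grid[order(grid$sex, grid$age), , drop = FALSE]
  structure(list(measure = measure, axis = axis, transform = transform,
                 sex_specific = !is.null(sex), grid = grid,
                 margin = margin, extrapolation = extrapolation),
            class = "ref_chart")
}

#' @export
print.ref_chart <- function(x, ...) {
  cat("Reference chart for '", x$measure, "' (", x$axis, ", ",
      x$transform, " scale",
      if (x$sex_specific) ", sex-specific", ")\n", sep = "")
  print(x$grid, row.names = FALSE)
  invisible(x)
}

interp_chart <- function(xs, ys, x, extrapolation = "linear") {
  y <- stats::approx(xs, ys, xout = x, rule = 2)$y
  if (identical(extrapolation, "linear")) {
    k <- length(xs)
    lo <- !is.na(x) & x < xs[1]
    hi <- !is.na(x) & x > xs[k]
    if (any(lo)) {
      s <- (ys[2] - ys[1]) / (xs[2] - xs[1])
      y[lo] <- ys[1] + s * (x[lo] - xs[1])
    }
    if (any(hi)) {
      s <- (ys[k] - ys[k - 1]) / (xs[k] - xs[k - 1])
      y[hi] <- ys[k] + s * (x[hi] - xs[k])
    }
  }
  y
}

chart_locate <- function(chart, age, sex) {
  grid <- chart$grid
  if (chart$sex_specific) {
    sex <- as.character(sex)
    if (anyNA(sex)) stop_eg("sex required for a sex-specific chart")
  } else sex <- rep("all", length(age))
  mu <- sd <- rep(NA_real_, length(age))
  for (s in unique(sex)) {
    g <- grid[grid$sex == s, , drop = FALSE]
    if (nrow(g) == 0L) stop_eg("no chart for sex '", s, "'")
    i <- which(sex == s)
    lo <- min(g$age) - chart$margin
    hi <- max(g$age) + chart$margin
    bad <- !is.na(age[i]) & (age[i] < lo | age[i] > hi)
    if (any(bad))
      stop_eg("age ", format(age[i][bad][1]), " outside chart range [",
              format(lo), ", ", format(hi), "] for '", chart$measure, "'")
    if (nrow(g) == 1L) {
      mu[i] <- g$mean; sd[i] <- g$sd
    } else {
      mu[i] <- interp_chart(g$age, g$mean, age[i], chart$extrapolation)
      sd[i] <- interp_chart(g$age, g$sd, age[i], chart$extrapolation)
      # a linearly extrapolated SD must stay usable
      sd[i] <- pmax(sd[i], 0.25 * min(g$sd))
    }
  }
  list(mean = mu, sd = sd)
}

#' Standard deviation score against a reference chart
#'
#' `(transformed value - interpolated reference mean) / interpolated
#' reference SD`, with linear interpolation between chart ages and
#' constant extrapolation within the chart's margin. Missing values
#' propagate as missing; ages outside the chart margin error.
#'
#' @param value Measurement (raw scale; the chart's transform is applied
#'   internally).
#' @param age Age on the chart's axis.
#' @param chart A [fit_reference()] chart.
#' @param sex Sex, required for sex-specific charts.
#' @return Numeric SDS vector.
#' @export
sds <- function(value, age, chart, sex = NULL) {
  stopifnot(inherits(chart, "ref_chart"))
  n <- max(length(value), length(age))
  value <- rep_len(value, n); age <- rep_len(age, n)
  if (!is.null(sex)) sex <- rep_len(as.character(sex), n)
  out <- rep(NA_real_, n)
  ok <- !is.na(value) & !is.na(age)
  if (chart$sex_specific) ok <- ok & !is.na(sex)
  if (!any(ok)) return(out)
  v <- value[ok]
  if (chart$transform == "log") {
    if (any(v <= 0)) stop_eg("log-scale chart requires positive values")
    v <- log(v)
  }
  loc <- chart_locate(chart, age[ok], if (is.null(sex)) NULL else sex[ok])
  out[ok] <- (v - loc$mean) / loc$sd
  out
}

#' Classify birth size from birth-weight SDS
#'
#' Small for gestational age (SGA) is birth-weight SDS below the 5th
#' percentile, large for gestational age (LGA) above the 95th, appropriate
#' (AGA) otherwise. By default the percentile cutoffs are mapped to
#' z-cutoffs assuming the SDS are standard normal (qnorm(0.05) etc.);
#' `empirical = TRUE` instead uses the sample's own empirical quantiles.
#' Inequalities are strict, so values exactly on a cutoff are AGA.
#'
#' @param birth_sds Birth-weight SDS vector.
#' @param percentiles Lower/upper percentile cutoffs, default `c(.05, .95)`.
#' @param empirical Use empirical quantiles of `birth_sds` as cutoffs.
#' @return Factor with levels `SGA`, `AGA`, `LGA`; `NA` propagates.
#' @export
classify_birth_size <- function(birth_sds, percentiles = c(0.05, 0.95),
                                empirical = FALSE) {
  stopifnot(length(percentiles) == 2L, percentiles[1] < percentiles[2])
  cut_lo <- if (empirical)
    stats::quantile(birth_sds, percentiles[1], na.rm = TRUE) else
    stats::qnorm(percentiles[1])
  cut_hi <- if (empirical)
    stats::quantile(birth_sds, percentiles[2], na.rm = TRUE) else
    stats::qnorm(percentiles[2])
  out <- ifelse(is.na(birth_sds), NA_character_,
                ifelse(birth_sds < cut_lo, "SGA",
                       ifelse(birth_sds > cut_hi, "LGA", "AGA")))
  factor(out, levels = c("SGA", "AGA", "LGA"))
}

#' Write / read a reference chart as delimited text
#'
#' @param chart A `ref_chart`.
#' @param path File path.
#' @return `read_chart` returns a `ref_chart`; `write_chart` its path,
#'   invisibly.
#' @export
write_chart <- function(chart, path) {
  stopifnot(inherits(chart, "ref_chart"))
  g <- chart$grid
  g$measure <- chart$measure; g$axis <- chart$axis
  g$transform <- chart$transform; g$margin <- chart$margin
  g$extrapolation <- chart$extrapolation %||% "linear"
  utils::write.csv(g[, c("measure", "axis", "transform", "margin",
                         "extrapolation", "sex", "age", "mean", "sd")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chart
#' @export
read_chart <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("measure", "axis", "transform", "margin", "sex", "age",
            "mean", "sd")
  if (!all(need %in% names(g)))
    stop_eg("chart file missing columns: ",
            paste(setdiff(need, names(g)), collapse = ", "))
  structure(list(measure = g$measure[1], axis = g$axis[1],
                 transform = g$transform[1],
                 sex_specific = !all(g$sex == "all"),
                 grid = g[, c("sex", "age", "mean", "sd")],
                 margin = g$margin[1],
                 extrapolation = if ("extrapolation" %in% names(g))
                   g$extrapolation[1] else "linear"),
            class = "ref_chart")
}
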