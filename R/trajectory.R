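#' Fit the Reed1 infant weight model
#'
#' Reed1 describes infant weight as \eqn{W(t) = A + Bt + C\ln t + D/t}
#' (t in years), linear in its parameters. Models are fitted for boys and
#' girls separately. The default structure is a per-sex mixed model with
#' random child intercept (A) and linear slope (B), estimated by maximum
#' likelihood; `method = "ols"` instead uses per-sex pooled OLS for the
#' fixed curve and a per-child OLS fit for children with at least
#' `min_obs_ols` observations (others keep the sex curve).
#' If a mixed fit fails it falls back to pooled OLS with child offsets of
#' zero, with a warning.
#'
#' @param data Data frame with columns `child`, `sex`, `age` (years) and
#'   `weight` (kg).
#' @param method `"mixed"` (default) or `"ols"`.
#' @param min_obs_ols Minimum observations per child for a per-child OLS
#'   curve, default 4.
#' @param window Admissible age window in years for the velocity peak,
#'   default `c(0, 1.5)`; peaks outside are flagged, not truncated.
#' @return Object of class `reed1_fit`: per-sex fixed coefficients and a
#'   per-child coefficient table.
#' @export
fit_reed1 <- function(data, method = c("mixed", "ols"),
                      min_obs_ols = 4L, window = c(0, 1.5)) {
  method <- match.arg(method)
  need <- c("child", "sex", "age", "weight")
  if (!all(need %in% names(data)))
    stop_eg("data must have columns ", paste(need, collapse = ", "))
  d <- data[stats::complete.cases(data[, need]), need]
  if (any(d$age < 2 / 52 - 1e-9))
    stop_eg("Reed1 requires ages of at least 2 weeks (t = 0 undefined)")
  d$lt <- log(d$age); d$it <- 1 / d$age
  fixed <- list(); children <- list()
  for (s in unique(as.character(d$sex))) {
    ds <- d[d$sex == s, , drop = FALSE]
    if (length(unique(ds$age)) < 4L)
      stop_eg("singular Reed1 basis for sex '", s,
              "': fewer than 4 distinct ages")
    fe <- NULL; ranefs <- NULL
    if (method == "mixed") {
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(weight ~ age + lt + it + (1 + age | child),
                     data = ds, REML = FALSE,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore",
                       check.nobs.vs.nRE = "ignore")))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        fe <- lme4::fixef(fit)
        ranefs <- lme4::ranef(fit)$child
      } else {
        warning("mixed Reed1 fit failed for sex '", s,
                "'; falling back to pooled OLS with zero child offsets",
                call. = FALSE)
      }
    }
    if (is.null(fe)) {
      ols <- stats::lm(weight ~ age + lt + it, data = ds)
      fe <- stats::coef(ols)
    }
    names(fe) <- c("A", "B", "C", "D")
    fixed[[s]] <- fe
    ids <- unique(ds$child)
    kid <- data.frame(child = ids, sex = s,
                      A = fe[["A"]], B = fe[["B"]],
                      C = fe[["C"]], D = fe[["D"]],
                      n_obs = as.integer(table(ds$child)[as.character(ids)]))
    if (!is.null(ranefs)) {
      ix <- match(as.character(ids), rownames(ranefs))
      kid$A <- kid$A + ifelse(is.na(ix), 0, ranefs[ix, "(Intercept)"])
      kid$B <- kid$B + ifelse(is.na(ix), 0, ranefs[ix, "age"])
    } else if (method == "ols") {
      for (i in seq_along(ids)) {
        di <- ds[ds$child == ids[i], , drop = FALSE]
        if (nrow(di) >= min_obs_ols &&
            length(unique(di$age)) >= 4L) {
          b <- stats::coef(stats::lm(weight ~ age + lt + it, data = di))
          if (!anyNA(b)) kid[i, c("A", "B", "C", "D")] <- unname(b)
        }
      }
    }
    children[[s]] <- kid
  }
  structure(list(fixed = fixed, children = do.call(rbind, children),
                 method = method, window = window),
            class = "reed1_fit")
}

#' @export
print.reed1_fit <- function(x, ...) {
  cat("Reed1 infant weight model (", x$method, "), ",
      nrow(x$children), " children\n", sep = "")
  for (s in names(x$fixed)) {
    cat(" ", s, ": ", sep = "")
    cat(paste(names(x$fixed[[s]]),
              formatC(x$fixed[[s]], digits = 4, format = "f"),
              sep = "="), sep = "  ")
    cat("\n")
  }
  invisible(x)
}

#' @export
coef.reed1_fit <- function(object, ...) object$fixed

#' @export
predict.reed1_fit <- function(object, newdata, ...) {
  k <- object$children[match(newdata$child, object$children$child), ]
  t <- newdata$age
  if (any(t <= 0)) stop_eg("Reed1 curve undefined at t <= 0")
  k$A + k$B * t + k$C * log(t) + k$D / t
}

#' Peak weight velocity from a Reed1 fit
#'
#' The weight velocity is \eqn{v(t) = B + C/t - D/t^2}. With C > 0 and
#' D > 0 the velocity has an interior maximum at \eqn{t^* = 2D/C} with
#' \eqn{PWV = B + C^2/(4D)}. When the interior peak does not exist or
#' falls outside the admissible window, the velocity is maximized over
#' the window boundary and the result is flagged non-interior.
#'
#' @param fit A [fit_reed1()] object.
#' @param children Optional subset of child ids (default: all).
#' @return Data frame: child, t_peak (years), pwv (kg/year), interior
#'   flag.
#' @export
peak_weight_velocity <- function(fit, children = NULL) {
  stopifnot(inherits(fit, "reed1_fit"))
  k <- fit$children
  if (!is.null(children)) k <- k[k$child %in% children, , drop = FALSE]
  lo <- max(fit$window[1], 2 / 52); hi <- fit$window[2]
  v <- function(B, C, D, t) B + C / t - D / t^2
  t_peak <- ifelse(k$C > 0 & k$D > 0, 2 * k$D / k$C, NA_real_)
  interior <- !is.na(t_peak) & t_peak > lo & t_peak <= hi
  pwv <- ifelse(interior, k$B + k$C^2 / (4 * k$D), NA_real_)
  bnd <- !interior
  if (any(bnd)) {
    v_lo <- v(k$B[bnd], k$C[bnd], k$D[bnd], lo)
    v_hi <- v(k$B[bnd], k$C[bnd], k$D[bnd], hi)
    pwv[bnd] <- pmax(v_lo, v_hi)
    t_peak[bnd] <- ifelse(v_lo >= v_hi, lo, hi)
  }
  data.frame(child = k$child, t_peak = t_peak, pwv = pwv,
             interior = interior)
}

#' Fit a cubic mixed model on log BMI in infancy
#'
#' \eqn{\log BMI = \beta_0 + \beta_1 t + \beta_2 t^2 + \beta_3 t^3} with a
#' sex main effect, t in months over the window 2 weeks to 1.5 years
#' (0.5 to 18 months; observations outside are dropped). Random child
#' intercept and linear term, maximum likelihood; falls back to pooled
#' OLS with zero offsets, with a warning, if the mixed fit fails.
#'
#' @param data Data frame with columns `child`, `sex`, `age` (months) and
#'   `bmi` (kg/m^2).
#' @param window Age window in months, default `c(0.5, 18)`.
#' @param method `"mixed"` (default) or `"ols"` (pooled OLS, no offsets).
#' @return Object of class `logbmi_cubic_fit`.
#' @export
fit_logbmi_cubic <- function(data, window = c(0.5, 18),
                             method = c("mixed", "ols")) {
  method <- match.arg(method)
  need <- c("child", "sex", "age", "bmi")
  if (!all(need %in% names(data)))
    stop_eg("data must have columns ", paste(need, collapse = ", "))
  d <- data[stats::complete.cases(data[, need]), need]
  d <- d[d$age >= window[1] & d$age <= window[2], , drop = FALSE]
  if (length(unique(d$age)) < 4L)
    stop_eg("fewer than 4 distinct ages in the modelling window")
  if (any(d$bmi <= 0)) stop_eg("BMI must be positive")
  d$y <- log(d$bmi)
  d$sex <- factor(as.character(d$sex))
  has_sex <- nlevels(d$sex) > 1L
  fe <- NULL; ranefs <- NULL
  if (method == "mixed") {
    fml <- if (has_sex)
      y ~ age + I(age^2) + I(age^3) + sex + (1 + age | child) else
      y ~ age + I(age^2) + I(age^3) + (1 + age | child)
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = d, REML = FALSE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     check.nobs.vs.nRE = "ignore")))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fe <- lme4::fixef(fit)
      ranefs <- lme4::ranef(fit)$child
    } else {
      warning("mixed log-BMI fit failed; falling back to pooled OLS",
              call. = FALSE)
    }
  }
  if (is.null(fe)) {
    fml <- if (has_sex)
      y ~ age + I(age^2) + I(age^3) + sex else
      y ~ age + I(age^2) + I(age^3)
    fe <- stats::coef(stats::lm(fml, data = d))
  }
  beta <- unname(fe[c("(Intercept)", "age", "I(age^2)", "I(age^3)")])
  sex_term <- grep("^sex", names(fe), value = TRUE)
  sex_eff <- if (length(sex_term)) unname(fe[sex_term]) else 0
  sex_level <- if (length(sex_term)) sub("^sex", "", sex_term) else NA
  ids <- unique(d$child)
  kid <- data.frame(child = ids,
                    sex = as.character(d$sex[match(ids, d$child)]),
                    b0 = beta[1], b1 = beta[2],
                    n_obs = as.integer(table(d$child)[as.character(ids)]))
  if (!is.na(sex_level))
    kid$b0 <- kid$b0 + ifelse(kid$sex == sex_level, sex_eff, 0)
  if (!is.null(ranefs)) {
    ix <- match(as.character(ids), rownames(ranefs))
    kid$b0 <- kid$b0 + ifelse(is.na(ix), 0, ranefs[ix, "(Intercept)"])
    kid$b1 <- kid$b1 + ifelse(is.na(ix), 0, ranefs[ix, "age"])
  }
  structure(list(beta = stats::setNames(beta, c("b0", "b1", "b2", "b3")),
                 sex_effect = sex_eff, sex_level = sex_level,
                 children = kid, window = window, method = method),
            class = "logbmi_cubic_fit")
}

#' @export
print.logbmi_cubic_fit <- function(x, ...) {
  cat("Cubic log(BMI) model, ", nrow(x$children), " children; ",
      "window [", x$window[1], ", ", x$window[2], "] months\n", sep = "")
  print(round(x$beta, 6))
  invisible(x)
}

#' @export
coef.logbmi_cubic_fit <- function(object, ...) object$beta

#' @export
predict.logbmi_cubic_fit <- function(object, newdata, ...) {
  k <- object$children[match(newdata$child, object$children$child), ]
  t <- newdata$age
  exp(k$b0 + k$b1 * t + object$beta[["b2"]] * t^2 +
        object$beta[["b3"]] * t^3)
}

#' Age and BMI at adiposity peak from a cubic log-BMI fit
#'
#' Solves \eqn{3\beta_3 t^2 + 2\beta_2 t + \beta_1 = 0} for each child's
#' curve and selects the real root inside the modelling window where the
#' second derivative is negative (a local maximum). AGEAP is that root in
#' months; BMIAP is the fitted BMI there. Children without a qualifying
#' root get `NA` with `interior = FALSE`.
#'
#' @param fit A [fit_logbmi_cubic()] object.
#' @param children Optional subset of child ids.
#' @return Data frame: child, ageap (months), bmiap (kg/m^2), interior.
#' @export
adiposity_peak <- function(fit, children = NULL) {
  stopifnot(inherits(fit, "logbmi_cubic_fit"))
  k <- fit$children
  if (!is.null(children)) k <- k[k$child %in% children, , drop = FALSE]
  b2 <- fit$beta[["b2"]]; b3 <- fit$beta[["b3"]]
  lo <- fit$window[1]; hi <- fit$window[2]
  ageap <- bmiap <- rep(NA_real_, nrow(k))
  for (i in seq_len(nrow(k))) {
    b1 <- k$b1[i]
    roots <- if (abs(b3) < 1e-12) {
      if (abs(b2) < 1e-12) numeric(0) else -b1 / (2 * b2)
    } else {
      disc <- (2 * b2)^2 - 4 * (3 * b3) * b1
      if (disc < 0) numeric(0) else
        (-2 * b2 + c(-1, 1) * sqrt(disc)) / (2 * 3 * b3)
    }
    roots <- roots[roots >= lo & roots <= hi &
                     2 * b2 + 6 * b3 * roots < 0]
    if (length(roots)) {
      t <- roots[1]
      ageap[i] <- t
      bmiap[i] <- exp(k$b0[i] + b1 * t + b2 * t^2 + b3 * t^3)
    }
  }
  data.frame(child = k$child, ageap = ageap, bmiap = bmiap,
             interior = !is.na(ageap))
}
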