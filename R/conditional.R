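#' Conditional growth variables (standardized residuals on prior weights)
#'
#' For an ordered set of weight-SDS columns (e.g. 20 weeks, 30 weeks,
#' birth, 6, 12, 24 months), the conditional variable at time point k is
#' the standardized residual from an OLS regression of SDS_k on the SDS at
#' all earlier time points: growth information statistically independent
#' of prior size. A child contributes at time point k only with complete
#' data at k and every earlier time point, so each time point has its own
#' eligible subsample. The first time point's conditional variable is its
#' SDS, standardized.
#'
#' @param sds_matrix Data frame or matrix of SDS columns in time order.
#' @return Data frame of class `conditional_growth` with one standardized
#'   conditional column per input column (`NA` where ineligible), plus an
#'   `n_eligible` attribute.
#' @export
conditional_variables <- function(sds_matrix) {
  x <- as.data.frame(sds_matrix)
  if (ncol(x) < 1L) stop_eg("need at least one SDS column")
  nm <- colnames(x)
  out <- as.data.frame(matrix(NA_real_, nrow(x), ncol(x),
                              dimnames = list(NULL, paste0("cond_", nm))))
  n_elig <- integer(ncol(x))
  for (k in seq_len(ncol(x))) {
    elig <- stats::complete.cases(x[, seq_len(k), drop = FALSE])
    n_elig[k] <- sum(elig)
    if (n_elig[k] < k + 2L)
      stop_eg("fewer than ", k + 2L, " children with complete data ",
              "through time point '", nm[k], "'")
    y <- x[elig, k]
    if (k == 1L) {
      r <- y - mean(y)
    } else {
      X <- cbind(1, as.matrix(x[elig, seq_len(k - 1L), drop = FALSE]))
      qrX <- qr(X)
      if (qrX$rank < ncol(X))
        stop_eg("singular design (collinear prior weights) at time ",
                "point '", nm[k], "'")
      r <- stats::residuals(stats::lm.fit(X, y))
    }
    s <- stats::sd(r)
    if (!is.finite(s) || s <= .Machine$double.eps^0.5)
      stop_eg("degenerate (zero-variance) residuals at time point '",
              nm[k], "'; prior weights determine SDS exactly")
    out[elig, k] <- r / s
  }
  attr(out, "n_eligible") <- stats::setNames(n_elig, nm)
  class(out) <- c("conditional_growth", class(out))
  out
}

#' Critical-period models: outcome on each conditional growth variable
#'
#' Fits one linear model per (time point, outcome): outcome SDS regressed
#' on that time point's conditional variable plus covariates, on the time
#' point's own eligible subsample. The coefficient is the difference in
#' outcome SDS per 1-SDS change in weight at that age, independent of all
#' prior weights.
#'
#' @param conditional_set Result of [conditional_variables()].
#' @param outcome_sds Numeric outcome SDS vector (same children).
#' @param covariates Optional data frame of covariates.
#' @param outcome Name used for reporting.
#' @param min_n Minimum n below which a result is flagged unstable.
#' @return Data frame of association results (one row per time point).
#' @export
critical_period_model <- function(conditional_set, outcome_sds,
                                  covariates = NULL, outcome = "outcome",
                                  min_n = 30L) {
  stopifnot(inherits(conditional_set, "conditional_growth"))
  res <- lapply(names(conditional_set), function(cn) {
    dat <- data.frame(.y = outcome_sds, .x = conditional_set[[cn]])
    if (!is.null(covariates)) dat <- cbind(dat, covariates)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    r <- fit_lm_term(.y ~ ., dat, term = ".x",
                     model = "conditional", exposure = cn,
                     outcome = outcome)
    r$unstable <- r$n < min_n
    r
  })
  do.call(rbind, res)
}
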