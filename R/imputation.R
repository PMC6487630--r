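#' Multiple imputation of missing covariates by chained equations
#'
#' Generates `m` completed datasets by iterated conditional draws:
#' missing cells are initialized from the observed marginal, then each
#' covariate with missingness is regressed on the other covariates
#' (Bayesian linear regression for continuous, logistic with a
#' parameter-perturbation draw for binary covariates) and its missing
#' cells redrawn, cycling for `iterations` burn-in sweeps per dataset.
#' Only covariate columns are ever imputed; exposures and outcomes are
#' carried through untouched.
#'
#' @param data Data frame.
#' @param covariates Character vector of covariate columns to impute.
#'   Binary covariates must be coded 0/1 (or 2-level factors); all others
#'   are treated as continuous.
#' @param m Number of imputed datasets, default 5.
#' @param seed Integer seed; each dataset uses a derived sub-seed.
#' @param iterations Burn-in sweeps per dataset, default 10.
#' @param max_missing Maximum allowed missing fraction per covariate.
#' @return Object of class `imputation_set`: a list of `m` completed data
#'   frames, with the per-dataset seeds as an attribute.
#' @export
impute_covariates <- function(data, covariates, m = 5L, seed = 1L,
                              iterations = 10L, max_missing = 0.6) {
  miss_cols <- setdiff(covariates, names(data))
  if (length(miss_cols))
    stop_eg("covariates not in data: ", paste(miss_cols, collapse = ", "))
  work <- data[, covariates, drop = FALSE]
  fac2 <- vapply(work, function(x) is.factor(x) && nlevels(x) == 2L,
                 logical(1))
  fac_levels <- lapply(work[fac2], levels)
  work[fac2] <- lapply(work[fac2], function(x) as.numeric(x) - 1)
  if (!all(vapply(work, is.numeric, logical(1))))
    stop_eg("covariates must be numeric or 2-level factors")
  frac <- vapply(work, function(x) mean(is.na(x)), numeric(1))
  if (any(frac >= 1))
    stop_eg("covariate with no observed values: ",
            paste(covariates[frac >= 1], collapse = ", "))
  if (any(frac > max_missing))
    stop_eg("covariate exceeds max_missing (", max_missing, "): ",
            paste(covariates[frac > max_missing], collapse = ", "))
  binary <- vapply(work, is_binary01, logical(1))
  to_fill <- names(frac)[frac > 0]
  to_fill <- to_fill[order(frac[to_fill])]
  seeds <- vapply(seq_len(m), function(i) derive_seed(seed, paste0("imp", i)),
                  integer(1))
  sets <- lapply(seq_len(m), function(i) {
    set.seed(seeds[i])
    filled <- work
    for (v in to_fill) {
      na <- is.na(filled[[v]])
      filled[[v]][na] <- sample(filled[[v]][!na], sum(na), replace = TRUE)
    }
    if (length(to_fill))
      for (it in seq_len(iterations)) for (v in to_fill) {
        na <- is.na(work[[v]])
        X <- as.matrix(cbind(1, filled[, setdiff(covariates, v),
                                       drop = FALSE]))
        filled[[v]][na] <- impute_draw(filled[[v]][!na], X[!na, , drop = FALSE],
                                       X[na, , drop = FALSE], binary[[v]])
      }
    out <- data
    for (v in covariates) {
      col <- filled[[v]]
      if (fac2[[v]])
        col <- factor(fac_levels[[v]][col + 1], levels = fac_levels[[v]])
      out[[v]] <- col
    }
    out
  })
  structure(sets, class = "imputation_set", seeds = seeds,
            covariates = covariates)
}

# One conditional draw for the missing cells of a covariate.
impute_draw <- function(y_obs, X_obs, X_mis, binary) {
  qrX <- qr(X_obs)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  if (binary) {
    fit <- suppressWarnings(
      stats::glm.fit(X_obs, y_obs, family = stats::binomial()))
    # parameter draw from the asymptotic normal of the ML estimate
    w <- fit$weights
    XtWX <- crossprod(X_obs * sqrt(w))
    V <- tryCatch(solve(XtWX), error = function(e) NULL)
    beta <- fit$coefficients
    if (!is.null(V)) {
      L <- tryCatch(chol(V), error = function(e) NULL)
      if (!is.null(L))
        beta <- beta + drop(t(L) %*% stats::rnorm(length(beta)))
    }
    p <- stats::plogis(drop(X_mis %*% beta))
    stats::rbinom(nrow(X_mis), 1L, p)
  } else {
    fit <- stats::lm.fit(X_obs, y_obs)
    df <- length(y_obs) - fit$rank
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / stats::rchisq(1L, df)
    R <- qr.R(fit$qr)
    beta <- fit$coefficients +
      drop(backsolve(R, stats::rnorm(ncol(X_obs)))) * sqrt(sigma2)
    drop(X_mis %*% beta) + stats::rnorm(nrow(X_mis)) * sqrt(sigma2)
  }
}

#' Fit an association model on each imputed dataset and pool
#'
#' Convenience wrapper: [fit_association()] per completed dataset,
#' combined with [pool_rubin()].
#'
#' @param imputations An `imputation_set` (or list of data frames).
#' @param ... Passed to [fit_association()].
#' @return Pooled association results.
#' @export
pooled_association <- function(imputations, ...) {
  fits <- lapply(imputations, fit_association, ...)
  pool_rubin(fits)
}
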