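`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
stop_eg <- function(...) stop(..., call. = FALSE)

#' Piecewise-linear interpolation through anchor points
#'
#' Constant extrapolation beyond the outermost anchors.
#' @keywords internal
interp_anchor <- function(x, xs, ys) {
  stats::approx(xs, ys, xout = x, rule = 2)$y
}

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0L && all(x %in% c(0, 1))
}

#' Spawn a stream-specific seed from a master seed
#'
#' Keeps every stage's randomness a deterministic function of one master
#' seed while decoupling the streams. Result is a valid 32-bit integer.
#' @keywords internal
derive_seed <- function(seed, stream) {
  offsets <- c(cohort = 11L, charts = 23L, imputation = 37L, models = 53L,
               null = 71L, recovery = 89L)
  off <- if (stream %in% names(offsets)) offsets[[stream]] else
    sum(utf8ToInt(as.character(stream)))
  as.integer((as.numeric(seed) * 7919 + off) %% .Machine$integer.max)
}
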