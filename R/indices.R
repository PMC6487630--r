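#' Height powers used for the adiposity indices
#'
#' Integer powers by which height (in metres) is raised when building an
#' index uncorrelated with height: fat mass / height^4 (fat mass index),
#' fat-free mass / height^2 (fat-free mass index), visceral and
#' pericardial fat mass / height^3.
#' @export
default_height_powers <- c(fat_mass = 4, fat_free_mass = 2,
                           visceral = 3, pericardial = 3)

#' Estimate the height power that decorrelates an adiposity measure
#'
#' Regresses the natural log of the measure on the natural log of height;
#' the slope is the power by which height should be raised so that
#' measure/height^power is uncorrelated with height. The slope is also
#' rounded to the nearest integer (the form used for the published
#' indices) and the residual correlation of the unrounded index with
#' height is reported as a diagnostic.
#'
#' @param values Adiposity measure, strictly positive.
#' @param heights Heights, strictly positive (any consistent unit).
#' @param measure Name for reporting.
#' @return Object of class `allometric_power`: list with `measure`,
#'   `slope`, `rounded_power`, `decorrelation_corr`, `n`.
#' @export
estimate_power <- function(values, heights, measure = "measure") {
  ok <- !is.na(values) & !is.na(heights)
  values <- values[ok]; heights <- heights[ok]
  if (length(values) < 10L) stop_eg("need at least 10 observations")
  bad <- which(values <= 0 | heights <= 0)
  if (length(bad))
    stop_eg("nonpositive values at rows: ",
            paste(utils::head(bad, 5L), collapse = ", "))
  if (stats::sd(heights) == 0) stop_eg("constant heights: slope undefined")
  fit <- stats::lm(log(values) ~ log(heights))
  slope <- unname(stats::coef(fit)[2])
  idx <- values / heights^slope
  # an exact power law leaves a constant index: its correlation with
  # height is pure floating-point noise, so report 0
  dec <- if (stats::sd(stats::residuals(fit)) <
             1e-10 * stats::sd(log(values)))
    0 else stats::cor(idx, heights)
  structure(list(measure = measure, slope = slope,
                 rounded_power = round(slope),
                 decorrelation_corr = dec,
                 n = length(values)),
            class = "allometric_power")
}

#' @export
print.allometric_power <- function(x, ...) {
  cat(sprintf("Allometric power for %s: slope %.3f (rounded %d), n = %d\n",
              x$measure, x$slope, x$rounded_power, x$n))
  cat(sprintf("  corr(index, height) at unrounded power: %.4f\n",
              x$decorrelation_corr))
  invisible(x)
}

standardize <- function(x) {
  m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop_eg("zero standard deviation: SDS undefined")
  (x - m) / s
}

#' Build the childhood adiposity outcome panel
#'
#' From height, weight, DXA fat and fat-free mass, MRI visceral and
#' pericardial fat mass and liver fat fraction, computes BMI, fat mass
#' index (fat mass / height^4), fat-free mass index (/height^2), visceral
#' and pericardial fat indices (/height^3) with height in metres, and the
#' outcome SDS columns used by the association models. The skewed
#' measures (FMI, visceral index, liver fraction, pericardial index) are
#' natural-log-transformed before standardization; BMI and FFMI are
#' standardized on the raw scale. Each SDS column is standardized over
#' the children with that outcome observed (its own analysis sample).
#'
#' @param body Data frame with columns `height_cm`, `weight_kg`,
#'   `fat_mass_kg`, `fat_free_mass_kg`, `visceral_fat_g`,
#'   `pericardial_fat_g`, `liver_fat_pct` (any may be `NA`).
#' @param powers Height powers, default [default_height_powers].
#' @return Data frame: raw indices (`bmi`, `fmi`, `ffmi`,
#'   `visceral_index`, `pericardial_index`, `liver_fat_pct`) and SDS
#'   columns (`*_sds`). Nonpositive values under a log transform are
#'   excluded from that column with a message.
#' @export
build_outcomes <- function(body, powers = default_height_powers) {
  need <- c("height_cm", "weight_kg", "fat_mass_kg", "fat_free_mass_kg",
            "visceral_fat_g", "pericardial_fat_g", "liver_fat_pct")
  miss <- setdiff(need, names(body))
  if (length(miss))
    stop_eg("body data lacks columns: ", paste(miss, collapse = ", "))
  if (any(body$height_cm <= 0, na.rm = TRUE))
    stop_eg("heights must be positive")
  h <- body$height_cm / 100
  out <- data.frame(
    bmi = bmi(body$weight_kg, body$height_cm),
    fmi = body$fat_mass_kg / h^powers[["fat_mass"]],
    ffmi = body$fat_free_mass_kg / h^powers[["fat_free_mass"]],
    visceral_index = body$visceral_fat_g / h^powers[["visceral"]],
    pericardial_index = body$pericardial_fat_g / h^powers[["pericardial"]],
    liver_fat_pct = body$liver_fat_pct)
  log_cols <- c("fmi", "visceral_index", "liver_fat_pct",
                "pericardial_index")
  raw_cols <- c("bmi", "ffmi")
  for (cn in c(raw_cols, log_cols)) {
    x <- out[[cn]]
    if (cn %in% log_cols) {
      bad <- !is.na(x) & x <= 0
      if (any(bad)) {
        message(sum(bad), " nonpositive value(s) of ", cn,
                " excluded from log-SDS")
        x[bad] <- NA
      }
      x <- log(x)
    }
    out[[paste0(cn, "_sds")]] <- standardize(x)
  }
  out
}
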