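#' Hadlock coefficients for estimated fetal weight
#'
#' Coefficients of the three-biometric (head circumference, abdominal
#' circumference, femur length) Hadlock formula,
#' \deqn{\log_{10} EFW = 1.326 - 0.00326\,AC\,FL + 0.0107\,HC + 0.0438\,AC
#'   + 0.158\,FL,}
#' with all biometry in centimetres and EFW in grams. Exposed read-only so
#' users can audit (or, via the `coefficients` argument of
#' [estimated_fetal_weight()], override) the variant in use.
#'
#' @format Named numeric vector with elements `intercept`, `ac_fl`, `hc`,
#'   `ac`, `fl`.
#' @export
hadlock_coefficients <- c(
  intercept = 1.326, ac_fl = -0.00326, hc = 0.0107, ac = 0.0438, fl = 0.158
)

#' Estimated fetal weight from ultrasound biometry (Hadlock)
#'
#' Computes estimated fetal weight in grams from head circumference,
#' abdominal circumference and femur length, all in centimetres. Inputs are
#' vectorised; `NA` propagates.
#'
#' @param hc Head circumference, cm.
#' @param ac Abdominal circumference, cm.
#' @param fl Femur length, cm.
#' @param coefficients Formula coefficients; defaults to
#'   [hadlock_coefficients].
#' @param allow_mm If `TRUE`, biometry with HC or AC above 100 is treated as
#'   millimetres and divided by 10. Default is strict centimetres: such
#'   values raise an error rather than being silently converted.
#' @return Estimated fetal weight in grams.
#' @examples
#' estimated_fetal_weight(hc = 17.5, ac = 15.0, fl = 3.0) # ~314.5 g
#' @export
estimated_fetal_weight <- function(hc, ac, fl,
                                   coefficients = hadlock_coefficients,
                                   allow_mm = FALSE) {
  if (any(c(hc, ac, fl) <= 0, na.rm = TRUE))
    stop_eg("biometry must be strictly positive")
  big <- !is.na(hc) & !is.na(ac) & (hc > 100 | ac > 100)
  if (any(big)) {
    if (!allow_mm)
      stop_eg("biometry looks like millimetres (HC or AC > 100); ",
              "supply centimetres or set allow_mm = TRUE")
    hc[big] <- hc[big] / 10
    ac[big] <- ac[big] / 10
    fl[big] <- fl[big] / 10
  }
  k <- coefficients
  expo <- k[["intercept"]] + k[["ac_fl"]] * ac * fl + k[["hc"]] * hc +
    k[["ac"]] * ac + k[["fl"]] * fl
  10^expo
}

#' Body mass index
#'
#' @param weight_kg Weight in kilograms.
#' @param height_cm Height in centimetres.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_cm) {
  if (any(height_cm <= 0, na.rm = TRUE))
    stop_eg("height must be strictly positive")
  weight_kg / (height_cm / 100)^2
}

#' Adipose tissue volume to mass
#'
#' Converts an MRI fat volume (mL) to mass (g) using the specific gravity
#' of adipose tissue, 0.9 g/mL.
#'
#' @param volume_ml Fat volume in millilitres.
#' @return Fat mass in grams.
#' @export
fat_volume_to_mass <- function(volume_ml) {
  if (any(volume_ml < 0, na.rm = TRUE))
    stop_eg("volume must be nonnegative")
  volume_ml * 0.9
}

#' Overall liver fat fraction from regional samples
#'
#' Arithmetic mean of per-region proton-density fat-fraction samples
#' (percent). The acquisition standard is four hepatic samples; any
#' positive number is accepted.
#'
#' @param samples Numeric vector of fat-fraction samples, percent.
#' @param na_rm Drop missing samples before averaging.
#' @return Mean fat fraction, percent.
#' @export
liver_fat_fraction <- function(samples, na_rm = TRUE) {
  if (na_rm) samples <- samples[!is.na(samples)]
  if (length(samples) == 0L)
    stop_eg("at least one liver fat-fraction sample is required")
  mean(samples)
}
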