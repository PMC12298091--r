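# Analytic tonometry correction formulas.
#
# Classical corrections for Goldmann applanation readings (IOPG), kept here
# as reference comparators for the learned pipeline. Clinical input takes
# central corneal thickness (CCT) in micrometres; formulas defined on
# millimetres convert internally. None of these is endorsed clinically.

#' Ehlers central-corneal-thickness correction
#'
#' `IOP = IOPG - 5.0 * ((CCT/1000 - 0.520) / 0.070)` with CCT in micrometres:
#' the correction vanishes at the 520 um reference thickness and changes by
#' 5 mmHg per 70 um of deviation.
#'
#' @param iopg Goldmann reading, mmHg.
#' @param cct central corneal thickness, micrometres (> 0).
#' @return corrected IOP, mmHg.
#' @export
ehlers_correct <- function(iopg, cct) {
  if (any(cct <= 0)) stop("`cct` must be positive (micrometres)", call. = FALSE)
  iopg - 5.0 * (((cct / 1000) - 0.520) / 0.070)
}

#' Thin-shell correction factor
#'
#' `IOP = IOPG / K`, where `K` is a correction factor depending on corneal
#' dimensions, radius and thickness (supplied by the caller).
#'
#' @param iopg Goldmann reading, mmHg.
#' @param K correction factor (> 0).
#' @return corrected IOP, mmHg.
#' @export
shell_correct <- function(iopg, K) {
  if (any(K <= 0)) stop("`K` must be positive", call. = FALSE)
  iopg / K
}

#' Linear pachymetry correction
#'
#' `IOP = IOPG + (23.28 - 0.0423 * CCT)` with CCT in micrometres.
#'
#' @param iopg Goldmann reading, mmHg.
#' @param cct central corneal thickness, micrometres.
#' @return corrected IOP, mmHg.
#' @export
linear_correct <- function(iopg, cct) {
  iopg + (23.28 - 0.0423 * cct)
}

#' Multiparameter (finite-element derived) correction factor
#'
#' `C = A_CCT * (CCT - 0.520)^2 + A_R * (R - 7.8) + A_Age * Age + A_IOPG`,
#' with CCT in micrometres on input (converted to millimetres), anterior
#' curvature radius `R` in millimetres and age in years. The coefficients are
#' caller-supplied (they come from the finite-element literature and are not
#' defaulted here). The corrected pressure is `IOPG / C`.
#'
#' @param iopg Goldmann reading, mmHg.
#' @param cct central corneal thickness, micrometres (> 0).
#' @param R anterior curvature radius, millimetres (> 0).
#' @param age age in years.
#' @param A_CCT,A_R,A_Age,A_IOPG correction coefficients.
#' @return list with `C` (correction factor) and `iop` (corrected IOP).
#' @export
elsheikh_factor <- function(iopg, cct, R, age, A_CCT, A_R, A_Age, A_IOPG) {
  if (any(cct <= 0)) stop("`cct` must be positive (micrometres)", call. = FALSE)
  if (any(R <= 0)) stop("`R` must be positive (millimetres)", call. = FALSE)
  cct_mm <- cct / 1000
  C <- A_CCT * (cct_mm - 0.520)^2 + A_R * (R - 7.8) + A_Age * age + A_IOPG
  if (any(C <= 0)) {
    stop("correction factor C must be positive; got C <= 0", call. = FALSE)
  }
  list(C = C, iop = iopg / C)
}
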