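## Erythemal (McKinlay-Diffey/CIE) UV dosimetry: action-spectrum weights,
## erythemally effective energy of a lamp dose, and SED conversions.

#' Erythemal action-spectrum weight
#'
#' The McKinlay-Diffey erythema reference action spectrum: weight 1 for
#' wavelengths up to 298 nm, \code{10^(0.094 (298 - lambda))} for
#' 298-328 nm and \code{10^(0.015 (C - lambda))} for 328-400 nm.  With
#' the default \code{C = 140} the third segment joins the second
#' continuously at 328 nm (the CIE-1998 form); \code{C = 139} selects the
#' original 1987 coefficients, which leave a small (< 10^-3) jump at
#' 328 nm.
#'
#' @param wavelength_nm numeric wavelengths in [250, 400] nm.
#' @param C third-segment constant, 140 (default) or 139.
#' @return Weights in (0, 1].
#' @export
erythemalWeight <- function(wavelength_nm, C = 140) {
  w <- wavelength_nm
  if (any(w < 250 | w > 400))
    stop("wavelength outside the [250, 400] nm domain")
  ifelse(w <= 298, 1,
  ifelse(w <= 328, 10^(0.094 * (298 - w)),
                   10^(0.015 * (C - w))))
}

#' Erythemally effective energy of a dose through a lamp spectrum
#'
#' Weights an unweighted energy dose by the erythemal effectiveness of
#' the lamp's emission spectrum:
#' \code{EEE = dose * integral(w(l) S(l) dl) / integral(S(l) dl)} with
#' trapezoidal integration on the native wavelength grid, so a two-point
#' spectrum reduces to the hand-computable two-point quadrature
#' \code{(w(l1) S1 + w(l2) S2) / (S1 + S2)}.  For a continuum spectrum
#' tabulated on a coarse grid the weight varies strongly within a grid
#' step; pass \code{resample_nm} to linearly resample the intensities
#' before weighting.  The result is linear in the dose, invariant to
#' rescaling the spectrum, and never exceeds the unweighted dose.
#'
#' @param spectrum a [SpectralIrradiance-class].
#' @param dose_mj_cm2 unweighted dose in mJ/cm^2 (1 kJ/m^2 = 100
#'   mJ/cm^2).
#' @param C passed to [erythemalWeight()].
#' @param resample_nm optional grid step (nm) to resample the spectrum
#'   to before integrating (default NULL: native grid).
#' @return Erythemally weighted dose in mJ/cm^2.
#' @export
effectiveDose <- function(spectrum, dose_mj_cm2, C = 140,
                          resample_nm = NULL) {
  if (dose_mj_cm2 < 0) stop("dose must be non-negative")
  w <- spectrum@wavelengths
  s <- spectrum@intensities
  if (sum(s) == 0) stop("spectrum has zero total intensity")
  if (!is.null(resample_nm)) {
    grid <- seq(min(w), max(w), by = resample_nm)
    s <- stats::approx(w, s, xout = grid)$y
    w <- grid
  }
  frac <- pracma::trapz(w, erythemalWeight(w, C) * s) / pracma::trapz(w, s)
  dose_mj_cm2 * frac
}

#' Convert kJ/m^2 to mJ/cm^2
#' @param kj_m2 dose in kJ/m^2.
#' @return dose in mJ/cm^2 (factor 100).
#' @export
kJm2TomJcm2 <- function(kj_m2) kj_m2 * 100

#' Standard erythema dose conversions
#'
#' One SED is 10 mJ/cm^2 of erythemally weighted UV.
#'
#' @param mj_cm2,sed erythemally weighted doses.
#' @return the converted dose.
#' @export
mJcm2ToSed <- function(mj_cm2) {
  if (any(mj_cm2 < 0)) stop("dose must be non-negative")
  mj_cm2 / 10
}

#' @rdname mJcm2ToSed
#' @export
sedTomJcm2 <- function(sed) {
  if (any(sed < 0)) stop("dose must be non-negative")
  sed * 10
}

#' Tanning-session UVA equivalence arithmetic
#'
#' Converts a tanning-session dose in SED to erythemally weighted
#' mJ/cm^2, attributes a fraction of it to the UVB content of the lamp
#' (the remainder being the UVA-attributable portion), and expresses
#' that portion as a multiple of a reference lamp's erythemally
#' effective energy.  With the defaults (4.5 SED per session, half
#' attributable to UVB) and a reference EEE of 14.2 mJ/cm^2 this
#' reproduces the arithmetic 4.5 SED -> 45 mJ/cm^2 -> 22.5 mJ/cm^2 UVA
#' -> ratio 22.5/14.2.
#'
#' @param session_sed tanning-session dose in SED (default 4.5).
#' @param uvb_fraction fraction of the erythemal dose attributable to
#'   UVB (default 0.5).
#' @param reference_eee_mj_cm2 reference erythemally effective energy in
#'   mJ/cm^2 to compare the UVA-attributable portion against.
#' @return list with session_mj_cm2, uva_mj_cm2 and (when a reference is
#'   given) ratio_to_reference.
#' @export
tanningSessionEquivalence <- function(session_sed = 4.5,
                                      uvb_fraction = 0.5,
                                      reference_eee_mj_cm2 = NULL) {
  if (session_sed < 0) stop("dose must be non-negative")
  total <- sedTomJcm2(session_sed)
  uva <- total * (1 - uvb_fraction)
  out <- list(session_mj_cm2 = total, uva_mj_cm2 = uva)
  if (!is.null(reference_eee_mj_cm2))
    out$ratio_to_reference <- uva / reference_eee_mj_cm2
  out
}
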