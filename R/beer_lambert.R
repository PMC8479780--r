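#' Concentration from absorbance (Beer-Lambert)
#'
#' `c = A / (epsilon * l)`, with `epsilon` in mM^-1 cm^-1 and the result in
#' micromolar. Used to check chromophore stock concentrations at the Q-band
#' maximum before mixing (605 nm for phycocyanobilin with
#' epsilon = 37.9 mM^-1 cm^-1; 690 nm for biliverdin with 30.8 mM^-1 cm^-1).
#'
#' @param A Absorbance (OD).
#' @param epsilon Molar extinction coefficient (mM^-1 cm^-1), > 0.
#' @param pathlength Cuvette pathlength (cm), > 0. Default 1 cm.
#' @return Concentration in uM.
#' @examples
#' concentration_from_absorbance(0.1137, 37.9) # 3 uM PCB
#' @export
concentration_from_absorbance <- function(A, epsilon, pathlength = 1) {
  if (!all(is.finite(epsilon)) || any(epsilon <= 0))
    stop("concentration_from_absorbance: epsilon must be > 0", call. = FALSE)
  if (!all(is.finite(pathlength)) || any(pathlength <= 0))
    stop("concentration_from_absorbance: pathlength must be > 0", call. = FALSE)
  # A = eps[mM^-1 cm^-1] * c[mM] * l[cm]; convert mM -> uM
  1000 * A / (epsilon * pathlength)
}

#' Post-mixing concentrations and molar excess
#'
#' Dilution arithmetic for mixing a protein stock into a chromophore
#' solution: each final concentration is `conc * vol / (vol_a + vol_b)`, and
#' the molar excess of component a over component b is reported both at full
#' precision and rounded to 2 significant figures (as quoted in assembly
#' protocols).
#'
#' @param vol_a,conc_a Volume (mL) and concentration (uM) of component a
#'   (typically the apo-protein stock).
#' @param vol_b,conc_b Volume (mL) and concentration (uM) of component b
#'   (typically the free chromophore solution).
#' @return A list with `final_a`, `final_b` (uM), `excess_ratio` and
#'   `excess_ratio_2sf`.
#' @examples
#' mixing_concentrations(0.5, 23, 2, 3) # 4.6 uM protein, 2.40 uM bilin, 1.9x
#' @export
mixing_concentrations <- function(vol_a, conc_a, vol_b, conc_b) {
  if (vol_a <= 0 || vol_b <= 0)
    stop("mixing_concentrations: volumes must be > 0", call. = FALSE)
  vt <- vol_a + vol_b
  fa <- conc_a * vol_a / vt
  fb <- conc_b * vol_b / vt
  r <- fa / fb
  list(final_a = fa, final_b = fb,
       excess_ratio = r, excess_ratio_2sf = signif(r, 2))
}
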