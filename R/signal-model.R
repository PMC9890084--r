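#' Post-contrast longitudinal relaxation time
#'
#' Fast-exchange linear relaxation model: `1/T1 = 1/T1_0 + r1 * C`. This is
#' the relationship that makes the MR signal a (nonlinear) reporter of
#' gadolinium concentration.
#'
#' @param c Gadolinium concentration in mM (>= 0, vectorised).
#' @param t1_0 Native (pre-contrast) T1 in seconds.
#' @param r1 Relaxivity in L mmol^-1 s^-1.
#' @return Post-contrast T1 in seconds.
#' @examples
#' t1_post_contrast(0, 1.736)          # native T1 back
#' t1_post_contrast(5, 1.736, r1 = 4.5)
#' @export
t1_post_contrast <- function(c, t1_0, r1 = 4.5) {
  stopifnot(
    "`t1_0` must be positive" = t1_0 > 0,
    "`r1` must be positive" = r1 > 0
  )
  if (any(c < 0)) stop("concentration must be >= 0", call. = FALSE)
  1 / (1 / t1_0 + r1 * c)
}

#' Forward saturation-recovery signal model
#'
#' Ideal saturation-recovery signal for a spoiled gradient-echo readout with
#' complete magnetization saturation and a single effective saturation time:
#' `S(t) = gain * (1 - exp(-ts * R1(t)))` with
#' `R1(t) = 1/t1_0 + r1 * C(t)`. The readout train and T2* decay are not
#' modelled; what matters here is the concave, saturating dependence of
#' signal on concentration, which is strong at a standard saturation time
#' (100 ms) and weak at a short one (23.5 ms).
#'
#' @param conc A `conc_curve` (gadolinium concentration vs time, mM).
#' @param t1_0 Native T1 of the tissue/blood generating the signal (s).
#' @param ts Saturation time (s).
#' @param gain Scanner gain (arbitrary signal units).
#' @param r1 Relaxivity (L mmol^-1 s^-1).
#' @param baseline_n Pre-contrast frame count stored on the output curve.
#' @return A `signal_curve` on the same time grid.
#' @examples
#' cc <- conc_curve(0:9, c(0, 0, 0, 0, 1, 4, 5, 3, 2, 1))
#' sr_signal(cc, t1_0 = 1.736, ts = 0.1)
#' @export
sr_signal <- function(conc, t1_0, ts, gain = 1, r1 = 4.5, baseline_n = 4L) {
  stopifnot(
    "`ts` must be positive" = ts > 0,
    "`gain` must be positive" = gain > 0
  )
  r1t <- 1 / t1_post_contrast(pmax(conc$value, 0), t1_0, r1)
  signal_curve(
    conc$time_s, gain * (1 - exp(-ts * r1t)),
    ts = ts, baseline_n = baseline_n
  )
}

#' Convert signal intensities to gadolinium concentration
#'
#' Relative signal-enhancement conversion
#' `C(t) = (S(t) - S(0)) / (r1 * T1b * S_LV(0))`, where `S(0)` is the
#' pre-contrast baseline of the converted curve and `S_LV(0)` the baseline
#' of the blood-pool (LV) curve from the same acquisition, so scanner gain
#' cancels. The conversion is exactly linear in the signal; it removes the
#' saturation nonlinearity only insofar as the signal itself is linear in
#' concentration, which is why short saturation times (or a learned
#' correction) are needed for the AIF. Negative values from noise below
#' baseline are retained to preserve linearity; clipping happens only inside
#' deconvolution preprocessing.
#'
#' @param sig A `signal_curve`.
#' @param s_lv0 Baseline signal of the blood-pool curve (same acquisition).
#' @param t1_blood Native T1 of blood (s).
#' @param r1 Relaxivity (L mmol^-1 s^-1).
#' @param baseline_n Number of pre-contrast frames for `S(0)`; defaults to
#'   the curve's own `baseline_n` attribute.
#' @return A `conc_curve` in mM.
#' @export
concentration_from_signal <- function(sig, s_lv0, t1_blood, r1 = 4.5,
                                      baseline_n = NULL) {
  if (!is.numeric(s_lv0) || length(s_lv0) != 1 || s_lv0 <= 0) {
    stop("`s_lv0` must be a positive blood-pool baseline signal", call. = FALSE)
  }
  stopifnot("`t1_blood` must be positive" = t1_blood > 0)
  s0 <- baseline_signal(sig, baseline_n)
  conc_curve(sig$time_s, (sig$value - s0) / (r1 * t1_blood * s_lv0))
}
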