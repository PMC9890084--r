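#' Acquisition parameters for saturation-recovery perfusion imaging
#'
#' Bundles the pulse-sequence and relaxometry constants needed by the signal
#' model: the saturation (preparation) times of the standard high-resolution
#' acquisition and of the low-resolution AIF acquisition, native T1 of blood
#' and myocardium, and the contrast-agent relaxivity. Field-strength presets
#' supply native T1 of blood (1.736 s at 3 T, 1.435 s at 1.5 T); any value
#' can be overridden.
#'
#' @param field_strength Main field in tesla, 1.5 or 3.0.
#' @param ts_standard Saturation time of the standard acquisition (s).
#' @param ts_aif Saturation time of the low-resolution AIF acquisition (s).
#' @param tr Repetition time (s). @param te Echo time (s).
#' @param flip_angle Readout flip angle (degrees).
#' @param t1_blood Native (pre-contrast) T1 of blood (s). Defaults to the
#'   field-strength preset.
#' @param t1_myo Native T1 of myocardium (s), used only by the simulator.
#' @param r1 Longitudinal relaxivity of the contrast agent
#'   (L mmol^-1 s^-1).
#' @return An object of class `acq_params` (a named list).
#' @examples
#' acq_params(3.0)
#' acq_params(1.5)$t1_blood
#' @export
acq_params <- function(field_strength = 3.0,
                       ts_standard = 0.100,
                       ts_aif = 0.0235,
                       tr = 0.0022,
                       te = 0.0010,
                       flip_angle = 15,
                       t1_blood = NULL,
                       t1_myo = NULL,
                       r1 = 4.5) {
  if (!field_strength %in% c(1.5, 3.0)) {
    stop("`field_strength` must be 1.5 or 3.0 tesla", call. = FALSE)
  }
  if (is.null(t1_blood)) t1_blood <- if (field_strength == 3.0) 1.736 else 1.435
  if (is.null(t1_myo)) t1_myo <- if (field_strength == 3.0) 1.2 else 1.0
  stopifnot(
    "`ts_aif` must satisfy 0 < ts_aif < ts_standard" =
      is.numeric(ts_aif) && ts_aif > 0 && ts_aif < ts_standard,
    "T1 values must be positive" = t1_blood > 0 && t1_myo > 0,
    "`r1` must be positive" = r1 > 0,
    "`tr` and `te` must be positive" = tr > 0 && te > 0
  )
  structure(
    list(
      field_strength = field_strength,
      ts_standard = ts_standard,
      ts_aif = ts_aif,
      tr = tr,
      te = te,
      flip_angle = flip_angle,
      t1_blood = t1_blood,
      t1_myo = t1_myo,
      r1 = r1
    ),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<acq_params> %.1f T saturation-recovery\n",
      "  TS standard/AIF: %.1f / %.1f ms; TR %.2f ms; flip %g deg\n",
      "  T1 blood %.3f s; T1 myo %.2f s; r1 %.2f L/mmol/s\n"
    ),
    x$field_strength, 1000 * x$ts_standard, 1000 * x$ts_aif,
    1000 * x$tr, x$flip_angle, x$t1_blood, x$t1_myo, x$r1
  ))
  invisible(x)
}
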