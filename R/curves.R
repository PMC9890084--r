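#' Signal-intensity and concentration time curves
#'
#' Curves are tibbles with columns `time_s` and `value`, so they compose
#' with dplyr/tidyr verbs and plot directly with ggplot2. A
#' `signal_curve` additionally carries the saturation time `ts` (s) and the
#' number of pre-contrast baseline frames `baseline_n` as attributes; a
#' `conc_curve` holds gadolinium concentration in mM.
#'
#' @param time_s Sample times in seconds, strictly increasing.
#' @param value Signal intensities (arbitrary units, finite) or
#'   concentrations (mM).
#' @param ts Saturation time of the acquisition the curve came from (s).
#' @param baseline_n Number of pre-contrast frames used to estimate the
#'   baseline signal.
#' @return A tibble of subclass `signal_curve` or `conc_curve`.
#' @examples
#' sc <- signal_curve(0:9, c(1, 1, 1, 1, 2, 8, 15, 12, 9, 7), ts = 0.1)
#' baseline_signal(sc)
#' @name curves
NULL

#' @rdname curves
#' @export
signal_curve <- function(time_s, value, ts, baseline_n = 4L) {
  check_curve_vectors(time_s, value)
  stopifnot(
    "`ts` must be a positive saturation time in seconds" =
      is.numeric(ts) && length(ts) == 1 && ts > 0,
    "`baseline_n` must be smaller than the curve length" =
      baseline_n >= 1 && baseline_n < length(value)
  )
  if (any(value < 0)) stop("signal intensities must be >= 0", call. = FALSE)
  out <- tibble::new_tibble(
    list(time_s = as.numeric(time_s), value = as.numeric(value)),
    nrow = length(time_s), class = "signal_curve"
  )
  attr(out, "ts") <- as.numeric(ts)
  attr(out, "baseline_n") <- as.integer(baseline_n)
  out
}

#' @rdname curves
#' @export
conc_curve <- function(time_s, value) {
  check_curve_vectors(time_s, value)
  tibble::new_tibble(
    list(time_s = as.numeric(time_s), value = as.numeric(value)),
    nrow = length(time_s), class = "conc_curve"
  )
}

check_curve_vectors <- function(time_s, value) {
  if (length(time_s) != length(value)) {
    stop("`time_s` and `value` must have the same length", call. = FALSE)
  }
  if (length(time_s) < 2) stop("a curve needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(time_s)) || any(!is.finite(value))) {
    stop("curve samples must be finite", call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname curves
#' @param curve A curve tibble (any data frame with `time_s` and `value`).
#' @export
baseline_signal <- function(curve, baseline_n = NULL) {
  n <- baseline_n %||% attr(curve, "baseline_n") %||% 4L
  mean(curve$value[seq_len(min(n, nrow(curve)))])
}

#' Sampling interval of a uniformly sampled curve
#'
#' @param curve A curve tibble.
#' @param tol Relative tolerance on grid uniformity.
#' @return The common spacing in seconds; errors if the grid is not uniform.
#' @export
curve_dt <- function(curve, tol = 1e-6) {
  d <- diff(curve$time_s)
  if (max(d) - min(d) > tol * max(d)) {
    stop("curve is not on a uniform time grid (resample first)", call. = FALSE)
  }
  mean(d)
}

curve_ts <- function(curve) {
  ts <- attr(curve, "ts")
  if (is.null(ts)) stop("curve carries no saturation time `ts`", call. = FALSE)
  ts
}

#' Read and write curve CSV files
#'
#' Curves are stored as two-column CSV (`time_s,value`). A JSON sidecar
#' (`<path>.json`) holds the acquisition context (saturation time, baseline
#' frame count) so signal curves round-trip with their metadata.
#'
#' @param curve A `signal_curve` or `conc_curve`.
#' @param path Path of the CSV file.
#' @return `read_curve()` returns the curve; `write_curve()` returns `path`
#'   invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(time_s = curve$time_s, value = curve$value),
    path, row.names = FALSE
  )
  meta <- list(class = class(curve)[[1]])
  if (inherits(curve, "signal_curve")) {
    meta$ts <- attr(curve, "ts")
    meta$baseline_n <- attr(curve, "baseline_n")
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (identical(meta$class, "signal_curve")) {
    signal_curve(df$time_s, df$value,
      ts = meta$ts,
      baseline_n = meta$baseline_n %||% 4L
    )
  } else {
    conc_curve(df$time_s, df$value)
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x
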