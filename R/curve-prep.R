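#' Detect contrast arrival in the blood pool
#'
#' Finds the first frame whose signal exceeds the pre-contrast baseline by
#' `k_sigma` baseline standard deviations. If the baseline is exactly flat
#' (sd = 0), the first frame exceeding 5% of the curve's dynamic range
#' above baseline is used instead.
#'
#' @param curve A `signal_curve` (or any tibble with `value`).
#' @param n_base Number of leading frames treated as pre-contrast baseline.
#' @param k_sigma Detection threshold in baseline standard deviations.
#' @return The arrival frame index (1-based).
#' @examples
#' sc <- signal_curve(0:7, c(1, 1, 1, 1, 1, 8, 20, 30), ts = 0.1)
#' detect_arrival(sc) # 6
#' @export
detect_arrival <- function(curve, n_base = 4L, k_sigma = 5) {
  v <- curve$value
  if (n_base < 2) stop("`n_base` must be >= 2", call. = FALSE)
  if (length(v) <= n_base) {
    stop("curve must be longer than `n_base`", call. = FALSE)
  }
  base <- v[seq_len(n_base)]
  sd_b <- stats::sd(base)
  thresh <- if (sd_b > 0) {
    mean(base) + k_sigma * sd_b
  } else {
    mean(base) + 0.05 * (max(v) - min(v))
  }
  idx <- which(v > thresh)
  if (length(idx) == 0) {
    stop("contrast arrival not found (curve never exceeds threshold)",
      call. = FALSE
    )
  }
  idx[[1]]
}

#' Crop a curve to start four beats before contrast arrival
#'
#' Keeps `n_pre` pre-contrast frames before the arrival index (clamped at
#' the curve start) and re-zeroes the time axis.
#'
#' @param curve A curve tibble.
#' @param arrival_index Arrival frame index from [detect_arrival()].
#' @param n_pre Number of pre-arrival frames to keep.
#' @return The cropped curve, time re-zeroed, with attributes preserved.
#' @export
crop_pre_contrast <- function(curve, arrival_index, n_pre = 4L) {
  stopifnot("`arrival_index` must be >= 1" = arrival_index >= 1)
  start <- max(1L, as.integer(arrival_index) - as.integer(n_pre))
  out <- curve[seq(start, nrow(curve)), ]
  out$time_s <- out$time_s - out$time_s[[1]]
  if (inherits(curve, "signal_curve")) {
    attr(out, "ts") <- attr(curve, "ts")
    attr(out, "baseline_n") <- attr(curve, "baseline_n")
    class(out) <- class(curve)
  }
  out
}

#' Fix a value vector to the network input length
#'
#' Truncates to the first `n` samples (dropping the late recirculation
#' tail) or pads by repeating the final value, so a step edge is never
#' introduced at the end of short curves.
#'
#' @param values Numeric vector (non-empty).
#' @param n Target length (the network uses 64 time points).
#' @return A numeric vector of length `n`.
#' @export
fix_length <- function(values, n = 64L) {
  if (length(values) == 0) stop("`values` must be non-empty", call. = FALSE)
  if (length(values) >= n) {
    values[seq_len(n)]
  } else {
    c(values, rep(values[[length(values)]], n - length(values)))
  }
}

#' Normalize a saturated/unsaturated AIF pair
#'
#' Both curves are divided by the maximum of the *saturated* curve -- the
#' only quantity available at inference time on single-sequence data -- so
#' the saturated input has maximum 1 while the unsaturated reference may
#' exceed 1. The divisor is stored as `scale` so predictions can be
#' unnormalized back to signal units for quantification.
#'
#' @param sat Saturated AIF values (length 64 after [fix_length()]).
#' @param unsat Unsaturated reference AIF values (same length).
#' @param dt Sampling interval in seconds.
#' @param arrival_index Arrival index bookkeeping carried with the pair.
#' @return An object of class `aif_pair` with fields `sat`, `unsat`,
#'   `scale`, `dt`, `arrival_index`.
#' @export
normalize_pair <- function(sat, unsat, dt = NA_real_, arrival_index = NA_integer_) {
  if (length(sat) != length(unsat)) {
    stop("`sat` and `unsat` must have the same length", call. = FALSE)
  }
  scale <- max(sat)
  if (!is.finite(scale) || scale <= 0) {
    stop("maximum of the saturated curve must be positive", call. = FALSE)
  }
  structure(
    list(
      sat = sat / scale, unsat = unsat / scale, scale = scale,
      dt = dt, arrival_index = arrival_index,
      # raw inputs kept so unnormalization is exact, not a rounding trip
      sat_raw = sat, unsat_raw = unsat
    ),
    class = "aif_pair"
  )
}

#' @rdname normalize_pair
#' @param pair An `aif_pair`.
#' @return `unnormalize_pair()` returns a list with `sat` and `unsat` in
#'   original signal units.
#' @export
unnormalize_pair <- function(pair) {
  stopifnot(inherits(pair, "aif_pair"))
  if (!is.null(pair$sat_raw)) {
    list(sat = pair$sat_raw, unsat = pair$unsat_raw)
  } else {
    list(sat = pair$sat * pair$scale, unsat = pair$unsat * pair$scale)
  }
}

#' Preprocess one dual-sequence pair into the network representation
#'
#' Runs the full preprocessing chain on a saturated/reference curve pair
#' sharing a time grid: arrival detection on the saturated curve, cropping
#' of both curves to start `n_pre` beats pre-arrival, length fixing to
#' `n`, and joint normalization by the saturated maximum.
#'
#' @param sat_curve,ref_curve `signal_curve`s on the same time grid.
#' @param n Network input length. @param n_pre Pre-arrival beats kept.
#' @param k_sigma Arrival detection threshold.
#' @return An `aif_pair`.
#' @export
prep_aif_pair <- function(sat_curve, ref_curve, n = 64L, n_pre = 4L,
                          k_sigma = 5) {
  arr <- detect_arrival(sat_curve, n_base = n_pre, k_sigma = k_sigma)
  sat_c <- crop_pre_contrast(sat_curve, arr, n_pre)
  ref_c <- crop_pre_contrast(ref_curve, arr, n_pre)
  normalize_pair(
    fix_length(sat_c$value, n), fix_length(ref_c$value, n),
    dt = curve_dt(sat_curve), arrival_index = arr
  )
}

#' Extract the AIF from blood-pool pixel curves
#'
#' Implements the bright-pixel region-of-interest rule: within the
#' blood-pool mask, pixels are ranked by their peak intensity and the AIF
#' is the average curve of the pixels whose peak is strictly greater than
#' the 75th percentile of peak values (linear-interpolation order-statistic
#' convention, `stats::quantile` type 7).
#'
#' @param pixel_curves Numeric matrix, one column per pixel, one row per
#'   frame (all pixels share the time grid).
#' @param time_s Frame times in seconds.
#' @param blood_mask Logical vector selecting blood-pool pixels (columns).
#' @param ts,baseline_n Acquisition context for the returned curve.
#' @return A `signal_curve`: the mean curve of the supra-threshold pixels.
#' @export
extract_aif_roi <- function(pixel_curves, time_s, blood_mask,
                            ts = 0.1, baseline_n = 4L) {
  stopifnot(is.matrix(pixel_curves))
  if (length(blood_mask) != ncol(pixel_curves)) {
    stop("`blood_mask` must have one entry per pixel column", call. = FALSE)
  }
  if (!any(blood_mask)) stop("blood-pool mask is empty", call. = FALSE)
  sel <- pixel_curves[, blood_mask, drop = FALSE]
  if (ncol(sel) < 4) stop("mask must select at least 4 pixels", call. = FALSE)
  peaks <- apply(sel, 2, max)
  q75 <- stats::quantile(peaks, 0.75, type = 7, names = FALSE)
  top <- peaks > q75
  if (!any(top)) top <- peaks >= max(peaks) # all-identical degenerate case
  signal_curve(time_s, rowMeans(sel[, top, drop = FALSE]),
    ts = ts, baseline_n = baseline_n
  )
}

#' Write and read batches of AIF pairs
#'
#' Each pair is written as one CSV (`columns sat, unsat`) with the scalar
#' fields in a JSON manifest for the batch.
#'
#' @param pairs A list of `aif_pair` objects.
#' @param dir Output directory (created if needed).
#' @return `write_pairs()` returns `dir` invisibly; `read_pairs()` the list
#'   of pairs.
#' @export
write_pairs <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- purrr::imap(pairs, function(p, i) {
    file <- sprintf("pair_%04d.csv", i)
    utils::write.csv(data.frame(sat = p$sat, unsat = p$unsat),
      file.path(dir, file),
      row.names = FALSE
    )
    list(
      file = file, scale = p$scale, dt = p$dt,
      arrival_index = p$arrival_index
    )
  })
  jsonlite::write_json(manifest, file.path(dir, "pairs.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "pairs.json"))
  purrr::map(manifest, function(m) {
    df <- utils::read.csv(file.path(dir, m$file))
    structure(
      list(
        sat = df$sat, unsat = df$unsat, scale = m$scale, dt = m$dt,
        arrival_index = m$arrival_index %||% NA_integer_
      ),
      class = "aif_pair"
    )
  })
}
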