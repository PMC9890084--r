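#' Normalized mean squared error between two curves
#'
#' `NMSE = 100 * sum((pred - ref)^2) / sum(ref^2)`, in percent. The
#' normalization by the total reference energy `sum(ref^2)` is one of
#' several conventions in use; it is stated here prominently because it
#' affects comparability of absolute NMSE values across software.
#'
#' @param pred Predicted values. @param ref Reference values (same length,
#'   not all zero).
#' @return NMSE in percent.
#' @examples
#' nmse(c(1, 2, 3), c(1, 2, 3)) # 0
#' nmse(1.1 * c(4, 5), c(4, 5)) # exactly 1
#' @export
nmse <- function(pred, ref) {
  if (length(pred) != length(ref)) {
    stop("`pred` and `ref` must have the same length", call. = FALSE)
  }
  denom <- sum(ref^2)
  if (denom == 0) stop("`ref` must not be all zero", call. = FALSE)
  100 * sum((pred - ref)^2) / denom
}

#' Shape metrics of a bolus curve: peak value, time-to-peak, FWHM
#'
#' Peak value is the curve maximum (in whatever units the curve carries,
#' e.g. normalized signal units). Time-to-peak is the time of the (first)
#' maximum measured from the curve origin -- for curves cropped with
#' [crop_pre_contrast()] this origin is four beats before contrast
#' arrival. FWHM is the distance between the two half-maximum crossings
#' found by linear interpolation after subtracting the pre-contrast
#' baseline; if the curve never falls back below half maximum on either
#' side, FWHM is `NA` and `fwhm_defined` is `FALSE`.
#'
#' @param curve A curve tibble (`time_s`, `value`).
#' @param baseline_n Frames used for baseline subtraction.
#' @return A one-row tibble: `pv`, `ttp`, `fwhm`, `fwhm_defined`.
#' @examples
#' tri <- conc_curve(0:10, c(0:5, 4:0) / 5)
#' curve_metrics(tri, baseline_n = 1) # pv 1, ttp 5, fwhm 5
#' @export
curve_metrics <- function(curve, baseline_n = NULL) {
  if (nrow(curve) < 3) stop("need at least 3 samples", call. = FALSE)
  t <- curve$time_s
  v <- curve$value
  i_pk <- which.max(v)
  pv <- v[i_pk]
  ttp <- t[i_pk] - t[1]

  base <- mean(v[seq_len(min(
    baseline_n %||% attr(curve, "baseline_n") %||% 4L,
    length(v)
  ))])
  vb <- v - base
  half <- vb[i_pk] / 2
  left <- NA_real_
  if (i_pk >= 2) {
    for (i in i_pk:2) {
      if (vb[i - 1] <= half && vb[i] > half) {
        left <- t[i - 1] + (half - vb[i - 1]) / (vb[i] - vb[i - 1]) *
          (t[i] - t[i - 1])
        break
      }
    }
  }
  right <- NA_real_
  if (i_pk < length(v)) {
    for (i in seq(i_pk, length(v) - 1)) {
      if (vb[i] > half && vb[i + 1] <= half) {
        right <- t[i] + (vb[i] - half) / (vb[i] - vb[i + 1]) * (t[i + 1] - t[i])
        break
      }
    }
  }
  defined <- is.finite(left) && is.finite(right)
  tibble::tibble(
    pv = pv, ttp = ttp,
    fwhm = if (defined) right - left else NA_real_,
    fwhm_defined = defined
  )
}

#' Bland-Altman agreement analysis with linear fit
#'
#' Bias is `mean(a - b)`; the 95% limits of agreement are
#' `bias +/- 1.96 * sd(a - b)` (sample SD, n-1 denominator). The linear
#' relationship is summarized by ordinary least squares of `a` on `b`
#' (slope, intercept, r-squared).
#'
#' @param a,b Paired measurements (equal length >= 2), e.g. MBF from two
#'   AIF sources.
#' @return An object of class `agreement_report` (one-row tibble): `bias`,
#'   `loa_low`, `loa_high`, `slope`, `intercept`, `r2`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length", call. = FALSE)
  }
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  fit <- stats::lm(a ~ b)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((a - mean(a))^2)
  out <- tibble::tibble(
    bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n = length(a)
  )
  class(out) <- c("agreement_report", class(out))
  attr(out, "pairs") <- tibble::tibble(a = a, b = b)
  out
}

#' Compare two cohorts of a curve or MBF metric
#'
#' Reports median and IQR (single width, Q3 - Q1, quartiles by linear
#' interpolation) for each sample and the two-sided Mann-Whitney U
#' (Wilcoxon rank-sum) p-value. With ties (common for bounded metrics) the
#' normal approximation is used, as in standard practice.
#'
#' @param metrics_a,metrics_b Numeric samples (non-empty).
#' @return A one-row tibble: `median_a`, `iqr_a`, `median_b`, `iqr_b`,
#'   `p_value`, `n_a`, `n_b`.
#' @export
compare_cohorts <- function(metrics_a, metrics_b) {
  if (length(metrics_a) == 0 || length(metrics_b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  p <- suppressWarnings(
    stats::wilcox.test(metrics_a, metrics_b, exact = NULL)$p.value
  )
  tibble::tibble(
    median_a = stats::median(metrics_a),
    iqr_a = unname(diff(stats::quantile(metrics_a, c(0.25, 0.75), type = 7))),
    median_b = stats::median(metrics_b),
    iqr_b = unname(diff(stats::quantile(metrics_b, c(0.25, 0.75), type = 7))),
    p_value = p,
    n_a = length(metrics_a), n_b = length(metrics_b)
  )
}

#' Diagnostic agreement between two classification sets
#'
#' Percentage of AHA segments (and, via [classify_vessel()], coronary
#' vessels) receiving the same normal/abnormal diagnosis from two AIF
#' sources.
#'
#' @param results_a,results_b Tibbles with `aha_id` and logical `abnormal`
#'   (matched segment ids; may span several subjects via an `id` column).
#' @return A one-row tibble: `n`, `n_match`, `agreement_pct`.
#' @export
diagnostic_agreement <- function(results_a, results_b) {
  keys <- intersect(c("id", "subject", "aha_id", "territory"), names(results_a))
  if (length(keys) == 0) stop("no id columns to match on", call. = FALSE)
  m <- dplyr::inner_join(
    dplyr::select(results_a, dplyr::all_of(keys), abn_a = "abnormal"),
    dplyr::select(results_b, dplyr::all_of(keys), abn_b = "abnormal"),
    by = keys
  )
  if (nrow(m) != nrow(results_a) || nrow(m) != nrow(results_b)) {
    stop("segment ids of the two result sets do not match", call. = FALSE)
  }
  tibble::tibble(
    n = nrow(m),
    n_match = sum(m$abn_a == m$abn_b),
    agreement_pct = 100 * sum(m$abn_a == m$abn_b) / nrow(m)
  )
}
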