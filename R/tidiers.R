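# broom-style methods and plots.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Fermi deconvolution fit
#'
#' @param x A `fermi_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`);
#'   `glance()`: a one-row fit summary.
#' @method tidy fermi_fit
#' @export
tidy.fermi_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mbf", "tau0", "k", "delay"),
    estimate = c(x$mbf, x$tau0, x$k, x$delay),
    unit = c("mL/min/g", "s", "1/s", "s")
  )
}

#' @rdname tidy.fermi_fit
#' @method glance fermi_fit
#' @export
glance.fermi_fit <- function(x, ...) {
  tibble::tibble(
    mbf = x$mbf, rss = x$rss, converged = x$converged, niter = x$niter
  )
}

#' Tidy a trained saturation-correction model
#'
#' @param x An `aif_model`.
#' @param ... Unused.
#' @return `tidy()`: the training history (one row per validation
#'   evaluation); `glance()`: a one-row model summary.
#' @method tidy aif_model
#' @export
tidy.aif_model <- function(x, ...) x$history

#' @rdname tidy.aif_model
#' @method glance aif_model
#' @export
glance.aif_model <- function(x, ...) {
  tibble::tibble(
    depth = x$unet_config$depth,
    base_channels = x$unet_config$base_channels,
    n_params = n_params(x$net),
    iterations = x$train_config$iterations,
    validation_loss = x$validation_loss
  )
}

#' Tidy an end-to-end evaluation
#'
#' @param x An `aif_evaluation`.
#' @param ... Unused.
#' @return `tidy()`: the per-segment table; `glance()`: the one-row
#'   headline summary (median NMSE, MBF bias and limits of agreement,
#'   diagnostic agreement).
#' @method tidy aif_evaluation
#' @export
tidy.aif_evaluation <- function(x, ...) x$segments

#' @rdname tidy.aif_evaluation
#' @method glance aif_evaluation
#' @export
glance.aif_evaluation <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subjects),
    n_segments = nrow(x$segments),
    median_nmse_pct = stats::median(x$curves$nmse_pred),
    median_nmse_uncorrected_pct = stats::median(x$curves$nmse_sat),
    mbf_bias = x$ba_segment$bias,
    loa_low = x$ba_segment$loa_low,
    loa_high = x$ba_segment$loa_high,
    segment_agreement_pct =
      x$agreement$agreement_pct[x$agreement$level == "segment"],
    vessel_agreement_pct =
      x$agreement$agreement_pct[x$agreement$level == "vessel"]
  )
}

#' Bland-Altman plot of an agreement report
#'
#' @param object An `agreement_report` from [bland_altman()].
#' @param ... Unused.
#' @return A ggplot: per-pair differences against means, with the bias and
#'   95% limits of agreement.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  pairs <- attr(object, "pairs")
  df <- tibble::tibble(
    mean = (pairs$a + pairs$b) / 2, diff = pairs$a - pairs$b
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high), linetype = 2
    ) +
    ggplot2::labs(
      x = "Mean of methods", y = "Difference",
      title = sprintf(
        "Bland-Altman: bias %.3f [%.3f, %.3f]",
        object$bias, object$loa_low, object$loa_high
      )
    ) +
    ggplot2::theme_minimal()
}

#' Overlay the AIF curves of one synthetic subject
#'
#' @param object A `synthetic_subject`.
#' @param ... Unused.
#' @return A ggplot of the saturated, reference, and true (concentration,
#'   scaled) AIF curves.
#' @method autoplot synthetic_subject
#' @export
autoplot.synthetic_subject <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(object$sat_aif), curve = "saturated (TS std)"),
    dplyr::mutate(tibble::as_tibble(object$ref_aif), curve = "reference (TS short)")
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_s, y = .data$value, colour = .data$curve
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (s)", y = "Signal (a.u.)",
      title = sprintf("%s: dual-sequence AIF pair", object$id)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a normalized AIF pair with an optional prediction
#'
#' @param pair An `aif_pair`.
#' @param prediction Optional predicted (normalized) curve to overlay.
#' @return A ggplot of the saturated input, unsaturated reference, and
#'   prediction in normalized units.
#' @export
plot_aif_pair <- function(pair, prediction = NULL) {
  n <- length(pair$sat)
  t <- if (is.finite(pair$dt)) seq(0, by = pair$dt, length.out = n) else seq_len(n)
  df <- dplyr::bind_rows(
    tibble::tibble(time_s = t, value = pair$sat, curve = "saturated input"),
    tibble::tibble(time_s = t, value = pair$unsat, curve = "unsaturated reference")
  )
  if (!is.null(prediction)) {
    df <- dplyr::bind_rows(
      df, tibble::tibble(time_s = t, value = prediction, curve = "prediction")
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_s, y = .data$value, colour = .data$curve
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Normalized signal") +
    ggplot2::theme_minimal()
}

#' Training-history plot of a model
#'
#' @param object An `aif_model`.
#' @param ... Unused.
#' @return A ggplot of training and validation MSE against iteration.
#' @method autoplot aif_model
#' @export
autoplot.aif_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_mse", "val_mse"),
    names_to = "set", values_to = "mse"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$iteration, y = .data$mse, colour = .data$set
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Iteration", y = "MSE (normalized units)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
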