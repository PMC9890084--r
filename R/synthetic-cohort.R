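#' Gamma-variate bolus parameters
#'
#' Parameterises the first-pass arterial concentration curve as a
#' normalized gamma-variate with optional recirculation: peak height in mM,
#' arrival time `t0`, shape `alpha` and timescale `beta` (the analytic
#' time-to-peak from arrival is `alpha * beta`), plus a recirculation bump
#' expressed as a delayed copy of the first pass convolved with an
#' exponential tail.
#'
#' @param t0 Bolus arrival time (s). @param alpha Shape (dimensionless).
#' @param beta Timescale (s). @param peak First-pass peak concentration (mM).
#' @param recirc_frac Recirculation fraction in `[0, 1)`.
#' @param recirc_delay Recirculation delay (s).
#' @param recirc_tau Exponential-tail time constant of recirculation (s).
#' @return An object of class `gamma_variate_params`.
#' @export
gamma_variate_params <- function(t0, alpha, beta, peak,
                                 recirc_frac = 0, recirc_delay = 12,
                                 recirc_tau = 6) {
  stopifnot(
    "`alpha`, `beta`, `peak` must be positive and `t0` >= 0" =
      alpha > 0 && beta > 0 && peak > 0 && t0 >= 0,
    "`recirc_frac` must be in [0, 1)" = recirc_frac >= 0 && recirc_frac < 1,
    "`recirc_delay` and `recirc_tau` must be positive" =
      recirc_delay > 0 && recirc_tau > 0
  )
  structure(
    list(
      t0 = t0, alpha = alpha, beta = beta, peak = peak,
      recirc_frac = recirc_frac, recirc_delay = recirc_delay,
      recirc_tau = recirc_tau
    ),
    class = "gamma_variate_params"
  )
}

gamma_variate_eval <- function(t, t0, alpha, beta, peak) {
  u <- t - t0
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- peak * (u[pos] / (alpha * beta))^alpha * exp(alpha - u[pos] / beta)
  out
}

#' Generate an arterial input function concentration curve
#'
#' Evaluates the normalized gamma-variate
#' `C(t) = peak * ((t - t0)/(alpha*beta))^alpha * exp(alpha - (t - t0)/beta)`
#' for `t > t0` (0 before arrival), whose maximum is exactly `peak` at
#' `t = t0 + alpha*beta`. If `recirc_frac > 0`, a recirculation term is
#' added: the first-pass curve delayed by `recirc_delay` and convolved with
#' a normalized exponential tail, scaled by `recirc_frac`.
#'
#' @param p A [gamma_variate_params()] object.
#' @param times Sample times (s), increasing; uniform spacing is required
#'   when recirculation is enabled.
#' @return A `conc_curve`.
#' @examples
#' p <- gamma_variate_params(t0 = 3, alpha = 2.5, beta = 1.2, peak = 5)
#' aif <- gen_aif_concentration(p, seq(0, 30, by = 0.8))
#' @export
gen_aif_concentration <- function(p, times) {
  stopifnot(inherits(p, "gamma_variate_params"))
  if (any(diff(times) <= 0)) stop("`times` must be increasing", call. = FALSE)
  v <- gamma_variate_eval(times, p$t0, p$alpha, p$beta, p$peak)
  if (p$recirc_frac > 0) {
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-6 * max(dt)) {
      stop("recirculation requires a uniform time grid", call. = FALSE)
    }
    dt <- mean(dt)
    delayed <- gamma_variate_eval(
      times, p$t0 + p$recirc_delay, p$alpha, p$beta, p$peak
    )
    kern <- exp(-(times - times[1]) / p$recirc_tau) / p$recirc_tau
    full <- stats::convolve(delayed, rev(kern), type = "open")
    v <- v + p$recirc_frac * dt * full[seq_along(times)]
  }
  conc_curve(times, v)
}

#' Fermi tissue impulse-response kinetics
#'
#' The tissue impulse response is modelled as a Fermi function
#' `R_F(u) = 1 / (1 + exp(k * (u - tau0)))`, a plateau of width `tau0`
#' (the vascular-transit shoulder) decaying at rate `k`, normalized to
#' `R(0) = 1` (i.e. `R(u) = R_F(u) * (1 + exp(-k * tau0))`) and scaled by
#' myocardial blood flow, so that `mbf` is exactly the initial amplitude
#' of the impulse response -- the quantity Fermi-constrained deconvolution
#' reports as MBF -- rather than being confounded with the shape
#' parameters. With time in seconds and MBF in mL/min/g (unit tissue
#' density), the tissue curve is
#' `C_t(t) = (mbf/60) * integral( C_a(tau - delay) * R(t - tau) dtau )`.
#'
#' @param mbf Myocardial blood flow (mL/min/g, >= 0).
#' @param tau0 Shoulder width (s, >= 0). @param k Decay rate (1/s, > 0).
#' @param delay Arterial-to-tissue delay (s, >= 0).
#' @return An object of class `fermi_kinetics`.
#' @export
fermi_kinetics <- function(mbf, tau0, k, delay = 0) {
  stopifnot(
    "`mbf` must be >= 0" = mbf >= 0,
    "`tau0` must be >= 0" = tau0 >= 0,
    "`k` must be > 0" = k > 0,
    "`delay` must be >= 0" = delay >= 0
  )
  structure(list(mbf = mbf, tau0 = tau0, k = k, delay = delay),
    class = "fermi_kinetics"
  )
}

fermi_response <- function(u, tau0, k) {
  (1 + exp(-k * tau0)) / (1 + exp(k * (u - tau0)))
}

#' Forward tissue-curve model (Fermi-constrained convolution)
#'
#' Convolves an arterial input with the Fermi impulse response of
#' [fermi_kinetics()]. The integral is evaluated by trapezoidal quadrature
#' on an internally refined grid (`refine` sub-samples per frame, linear
#' interpolation of the AIF) and then sampled back to the acquisition grid,
#' so the once-per-heartbeat sampling does not degrade the quadrature.
#'
#' @param aif A `conc_curve` on a uniform time grid.
#' @param kin A [fermi_kinetics()] object.
#' @param refine Grid-refinement factor for the quadrature.
#' @return A `conc_curve` of tissue concentration on the AIF grid.
#' @examples
#' p <- gamma_variate_params(3, 2.5, 1.2, 5)
#' aif <- gen_aif_concentration(p, seq(0, 40, by = 1))
#' gen_tissue_curve(aif, fermi_kinetics(2, tau0 = 4, k = 0.3, delay = 0.5))
#' @export
gen_tissue_curve <- function(aif, kin, refine = 10L) {
  stopifnot(inherits(kin, "fermi_kinetics"))
  dt <- curve_dt(aif)
  if (kin$mbf == 0) {
    return(conc_curve(aif$time_s, numeric(nrow(aif))))
  }
  tf <- seq(aif$time_s[1], aif$time_s[nrow(aif)], by = dt / refine)
  ca <- stats::approx(aif$time_s, aif$value, xout = tf - kin$delay, rule = 2)$y
  ca[tf - kin$delay < aif$time_s[1]] <- aif$value[1]
  rf <- fermi_response(tf - tf[1], kin$tau0, kin$k)
  dtf <- dt / refine
  full <- stats::convolve(ca, rev(rf), type = "open")[seq_along(tf)]
  # trapezoid: halve the two end contributions of each partial sum
  trap <- dtf * (full - 0.5 * (ca[1] * rf + ca * rf[1]))
  vt <- (kin$mbf / 60) * trap
  conc_curve(aif$time_s, vt[seq(1, length(tf), by = refine)])
}

#' Cohort configuration for the synthetic dual-sequence generator
#'
#' Defines the parameter distributions a simulated stress-perfusion patient
#' is drawn from. Defaults emulate adenosine-stress first-pass bolus curves
#' acquired once per heartbeat with a dual-sequence AIF slice: heart rates
#' of 60-120 bpm, gamma-variate bolus shapes whose cohort medians of
#' time-to-peak and width fall in the regime reported for clinical stress
#' AIFs, peak arterial concentrations of 2-3.5 mM, and segmental MBF drawn
#' from a normal (1.5-4.5 mL/min/g) or hypoperfused (0.4-1.3 mL/min/g)
#' range so that both diagnostic classes occur.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param fractions Train/validation/test split fractions (sum to 1).
#' @param seed Integer seed controlling every random draw.
#' @param heart_rate,t0,alpha,beta,peak,recirc_frac,recirc_delay Ranges
#'   (length-2 numeric `c(lo, hi)`) for uniform subject-level draws.
#' @param mbf_normal,mbf_abnormal Segmental MBF ranges (mL/min/g).
#' @param p_abnormal Probability that a segment is hypoperfused.
#' @param tau0,k,delay Ranges for segmental Fermi kinetics.
#' @param noise_frac Gaussian signal noise SD as a fraction of the baseline
#'   blood-pool signal.
#' @param n_beats Number of acquired frames (one per heartbeat).
#' @param gain Scanner gain of the standard acquisition (signal units).
#' @param field_strength Tesla, forwarded to [acq_params()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 50,
                          fractions = c(train = 0.7, val = 0.1, test = 0.2),
                          seed = 1L,
                          heart_rate = c(60, 120),
                          t0 = c(4, 7),
                          alpha = c(2.0, 3.0),
                          beta = c(1.2, 1.8),
                          peak = c(2.0, 3.5),
                          recirc_frac = c(0.10, 0.25),
                          recirc_delay = c(10, 15),
                          mbf_normal = c(1.5, 4.5),
                          mbf_abnormal = c(0.4, 1.3),
                          p_abnormal = 0.25,
                          tau0 = c(2, 5),
                          k = c(0.15, 0.5),
                          delay = c(0, 1.5),
                          noise_frac = 0.05,
                          n_beats = 56L,
                          gain = 100,
                          field_strength = 3.0) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8 ||
    any(fractions < 0)) {
    stop("`fractions` must be 3 non-negative numbers summing to 1",
      call. = FALSE
    )
  }
  names(fractions) <- c("train", "val", "test")
  structure(
    list(
      n_subjects = as.integer(n_subjects), fractions = fractions,
      seed = as.integer(seed), heart_rate = heart_rate, t0 = t0,
      alpha = alpha, beta = beta, peak = peak, recirc_frac = recirc_frac,
      recirc_delay = recirc_delay, mbf_normal = mbf_normal,
      mbf_abnormal = mbf_abnormal, p_abnormal = p_abnormal, tau0 = tau0,
      k = k, delay = delay, noise_frac = noise_frac,
      n_beats = as.integer(n_beats), gain = gain,
      field_strength = field_strength
    ),
    class = "cohort_config"
  )
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Simulate one dual-sequence stress-perfusion subject
#'
#' Draws subject-level bolus and heart-rate parameters and 16 segmental
#' Fermi kinetics from `config`, builds the ground-truth arterial and
#' tissue concentration curves, and renders both acquisitions through the
#' saturation-recovery signal model: the standard acquisition
#' (`ts_standard`, saturated AIF and tissue curves) and the low-saturation
#' AIF reference (`ts_aif`). The reference slice gain is set so its
#' pre-contrast baseline matches the standard acquisition (the role played
#' by proton-density normalization on the scanner), and Gaussian signal
#' noise is added to every rendered curve.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the subject is fully reproducible given
#'   (`config`, `seed`).
#' @param id Subject identifier string.
#' @return An object of class `synthetic_subject`: ground truth
#'   (`aif_true`, `tissue_true`, `segment_kinetics`), acquisitions
#'   (`sat_aif`, `ref_aif`, `tissue_signal`), and provenance fields.
#' @export
simulate_subject <- function(config = cohort_config(), seed = 1L,
                             id = sprintf("S%04d", seed)) {
  stopifnot(inherits(config, "cohort_config"))
  local_seed(seed)
  acq <- acq_params(config$field_strength)

  heart_rate <- runif1(config$heart_rate)
  dt <- 60 / heart_rate
  times <- seq(0, by = dt, length.out = config$n_beats)
  gamma <- gamma_variate_params(
    t0 = runif1(config$t0), alpha = runif1(config$alpha),
    beta = runif1(config$beta), peak = runif1(config$peak),
    recirc_frac = runif1(config$recirc_frac),
    recirc_delay = runif1(config$recirc_delay)
  )
  aif_true <- gen_aif_concentration(gamma, times)

  abnormal <- stats::runif(16) < config$p_abnormal
  segment_kinetics <- tibble::tibble(
    aha_id = 1:16,
    mbf = ifelse(abnormal,
      stats::runif(16, config$mbf_abnormal[1], config$mbf_abnormal[2]),
      stats::runif(16, config$mbf_normal[1], config$mbf_normal[2])
    ),
    tau0 = stats::runif(16, config$tau0[1], config$tau0[2]),
    k = stats::runif(16, config$k[1], config$k[2]),
    delay = stats::runif(16, config$delay[1], config$delay[2]),
    abnormal_true = abnormal
  )
  tissue_true <- purrr::pmap(
    segment_kinetics[, c("mbf", "tau0", "k", "delay")],
    function(mbf, tau0, k, delay) {
      gen_tissue_curve(aif_true, fermi_kinetics(mbf, tau0, k, delay))
    }
  )

  gain <- config$gain
  base_std <- 1 - exp(-acq$ts_standard / acq$t1_blood)
  base_ref <- 1 - exp(-acq$ts_aif / acq$t1_blood)
  gain_ref <- gain * base_std / base_ref
  noise_sd <- config$noise_frac * gain * base_std

  add_noise <- function(sig) {
    signal_curve(sig$time_s,
      pmax(sig$value + stats::rnorm(nrow(sig), 0, noise_sd), 0),
      ts = attr(sig, "ts"), baseline_n = attr(sig, "baseline_n")
    )
  }
  sat_aif <- add_noise(sr_signal(aif_true, acq$t1_blood, acq$ts_standard,
    gain = gain, r1 = acq$r1
  ))
  ref_aif <- add_noise(sr_signal(aif_true, acq$t1_blood, acq$ts_aif,
    gain = gain_ref, r1 = acq$r1
  ))
  tissue_signal <- purrr::map(tissue_true, function(ct) {
    add_noise(sr_signal(ct, acq$t1_myo, acq$ts_standard,
      gain = gain, r1 = acq$r1
    ))
  })

  structure(
    list(
      id = id, seed = as.integer(seed), heart_rate = heart_rate, acq = acq,
      gamma = gamma, aif_true = aif_true,
      segment_kinetics = segment_kinetics, tissue_true = tissue_true,
      sat_aif = sat_aif, ref_aif = ref_aif, tissue_signal = tissue_signal,
      noise_sd = noise_sd, gain = gain, gain_ref = gain_ref
    ),
    class = "synthetic_subject"
  )
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "<synthetic_subject> %s: HR %.0f bpm, %d frames, peak AIF %.2f mM\n",
    x$id, x$heart_rate, nrow(x$aif_true), max(x$aif_true$value)
  ))
  cat(sprintf(
    "  segment MBF %.2f-%.2f mL/min/g (%d hypoperfused)\n",
    min(x$segment_kinetics$mbf), max(x$segment_kinetics$mbf),
    sum(x$segment_kinetics$abnormal_true)
  ))
  invisible(x)
}

#' Generate a synthetic cohort with train/validation/test splits
#'
#' Simulates `config$n_subjects` independent subjects (each from its own
#' derived seed) and partitions them into disjoint train/validation/test
#' sets according to `config$fractions`. Split sizes are the largest-
#' remainder apportionment of the fractions, and assignment is a seeded
#' random permutation.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `train`, `val`,
#'   `test` (lists of `synthetic_subject`) and `config`.
#' @export
gen_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  sizes <- split_sizes(n, config$fractions)
  local_seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  assignment <- sample(rep(c("train", "val", "test"), times = sizes))
  subjects <- purrr::map(seq_len(n), function(i) {
    simulate_subject(config, seed = subject_seeds[i], id = sprintf("S%04d", i))
  })
  structure(
    list(
      train = subjects[assignment == "train"],
      val = subjects[assignment == "val"],
      test = subjects[assignment == "test"],
      config = config
    ),
    class = "synthetic_cohort"
  )
}

split_sizes <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_frac <- order(raw - sizes, decreasing = TRUE)
    sizes[order_frac[seq_len(rem)]] <- sizes[order_frac[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(sizes), names(fractions))
}

#' Ground-truth MBF table of a cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @return A tibble with one row per subject x segment: `id`, `split`,
#'   `aha_id`, true `mbf`, Fermi parameters, and the true diagnostic class.
#' @export
cohort_truth <- function(cohort) {
  purrr::map_dfr(c("train", "val", "test"), function(split) {
    purrr::map_dfr(cohort[[split]], function(s) {
      dplyr::mutate(s$segment_kinetics, id = s$id, split = split, .before = 1)
    })
  })
}

# Seed the RNG for the calling function, restoring the caller's RNG state
# when that function exits.
local_seed <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(seed)
}
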