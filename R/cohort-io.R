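# Cohort serialization: one directory per cohort, per-subject CSV curve
# tables plus a JSON manifest with ids, seeds, splits, acquisition context
# and the ground-truth kinetics.

#' Write and read a synthetic cohort directory
#'
#' Each subject gets four CSV files (`<id>_aif.csv` with the true,
#' saturated and reference AIFs; `<id>_tissue_true.csv` and
#' `<id>_tissue_signal.csv` with the 16 segment curves; `<id>_kinetics.csv`
#' with the ground-truth Fermi parameters). `manifest.json` records the
#' configuration, splits, seeds and gains so `read_cohort()` reconstructs
#' the cohort exactly.
#'
#' @param cohort A `synthetic_cohort` from [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` the
#'   reconstructed `synthetic_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = unclass(cohort$config),
    subjects = list()
  )
  for (split in c("train", "val", "test")) {
    for (s in cohort[[split]]) {
      aif <- data.frame(
        time_s = s$aif_true$time_s,
        aif_true = s$aif_true$value,
        sat_aif = s$sat_aif$value,
        ref_aif = s$ref_aif$value
      )
      utils::write.csv(aif, file.path(dir, paste0(s$id, "_aif.csv")),
        row.names = FALSE
      )
      tt <- do.call(cbind, lapply(s$tissue_true, function(x) x$value))
      ts_m <- do.call(cbind, lapply(s$tissue_signal, function(x) x$value))
      colnames(tt) <- colnames(ts_m) <- sprintf("seg%02d", 1:16)
      utils::write.csv(
        cbind(data.frame(time_s = s$aif_true$time_s), tt),
        file.path(dir, paste0(s$id, "_tissue_true.csv")),
        row.names = FALSE
      )
      utils::write.csv(
        cbind(data.frame(time_s = s$aif_true$time_s), ts_m),
        file.path(dir, paste0(s$id, "_tissue_signal.csv")),
        row.names = FALSE
      )
      utils::write.csv(s$segment_kinetics,
        file.path(dir, paste0(s$id, "_kinetics.csv")),
        row.names = FALSE
      )
      manifest$subjects[[length(manifest$subjects) + 1L]] <- list(
        id = s$id, split = split, seed = s$seed,
        heart_rate = s$heart_rate, gamma = unclass(s$gamma),
        noise_sd = s$noise_sd, gain = s$gain, gain_ref = s$gain_ref,
        field_strength = s$acq$field_strength
      )
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cfg <- manifest$config
  config <- cohort_config(
    n_subjects = cfg$n_subjects,
    fractions = unlist(cfg$fractions),
    seed = cfg$seed,
    heart_rate = unlist(cfg$heart_rate), t0 = unlist(cfg$t0),
    alpha = unlist(cfg$alpha), beta = unlist(cfg$beta),
    peak = unlist(cfg$peak), recirc_frac = unlist(cfg$recirc_frac),
    recirc_delay = unlist(cfg$recirc_delay),
    mbf_normal = unlist(cfg$mbf_normal),
    mbf_abnormal = unlist(cfg$mbf_abnormal),
    p_abnormal = cfg$p_abnormal, tau0 = unlist(cfg$tau0),
    k = unlist(cfg$k), delay = unlist(cfg$delay),
    noise_frac = cfg$noise_frac, n_beats = cfg$n_beats, gain = cfg$gain,
    field_strength = cfg$field_strength
  )
  out <- list(train = list(), val = list(), test = list(), config = config)
  for (m in manifest$subjects) {
    acq <- acq_params(m$field_strength)
    aif <- utils::read.csv(file.path(dir, paste0(m$id, "_aif.csv")))
    tt <- utils::read.csv(file.path(dir, paste0(m$id, "_tissue_true.csv")))
    tsg <- utils::read.csv(file.path(dir, paste0(m$id, "_tissue_signal.csv")))
    kin <- tibble::as_tibble(
      utils::read.csv(file.path(dir, paste0(m$id, "_kinetics.csv")))
    )
    subject <- structure(
      list(
        id = m$id, seed = m$seed, heart_rate = m$heart_rate, acq = acq,
        gamma = do.call(gamma_variate_params, m$gamma),
        aif_true = conc_curve(aif$time_s, aif$aif_true),
        segment_kinetics = kin,
        tissue_true = lapply(1:16, function(j) {
          conc_curve(tt$time_s, tt[[sprintf("seg%02d", j)]])
        }),
        sat_aif = signal_curve(aif$time_s, aif$sat_aif,
          ts = acq$ts_standard
        ),
        ref_aif = signal_curve(aif$time_s, aif$ref_aif, ts = acq$ts_aif),
        tissue_signal = lapply(1:16, function(j) {
          signal_curve(tsg$time_s, tsg[[sprintf("seg%02d", j)]],
            ts = acq$ts_standard
          )
        }),
        noise_sd = m$noise_sd, gain = m$gain, gain_ref = m$gain_ref
      ),
      class = "synthetic_subject"
    )
    out[[m$split]][[length(out[[m$split]]) + 1L]] <- subject
  }
  structure(out, class = "synthetic_cohort")
}

#' Build normalized training pairs from cohort subjects
#'
#' Preprocesses every subject's saturated/reference AIF acquisition pair
#' into the network's fixed-length normalized representation.
#'
#' @param subjects A list of `synthetic_subject`s or a `synthetic_cohort`
#'   split.
#' @param n,n_pre Preprocessing parameters (see [prep_aif_pair()]).
#' @return A list of `aif_pair` objects.
#' @export
cohort_pairs <- function(subjects, n = 64L, n_pre = 4L) {
  purrr::map(subjects, function(s) {
    prep_aif_pair(s$sat_aif, s$ref_aif, n = n, n_pre = n_pre)
  })
}
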