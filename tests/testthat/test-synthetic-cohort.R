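# Synthetic cohort generator: bolus shapes, tissue forward model,
# dual-sequence acquisitions, splits.

test_that("gamma-variate AIF has the analytic peak location and height", {
  p <- gamma_variate_params(t0 = 3, alpha = 2.5, beta = 1.2, peak = 5)
  aif <- gen_aif_concentration(p, seq(0, 40, by = 0.001))
  expect_equal(aif$time_s[which.max(aif$value)], 3 + 2.5 * 1.2,
    tolerance = 1e-3
  )
  expect_equal(max(aif$value), 5, tolerance = 1e-6)
  expect_true(all(aif$value[aif$time_s <= 3] == 0))
})

test_that("gamma-variate FWHM matches the dense-grid oracle", {
  f <- function(t) {
    u <- pmax(t - 3, 0)
    ifelse(t > 3, (u / 3)^2.5 * exp(2.5 - u / 1.2), 0)
  }
  oracle <- fwhm_oracle(f)
  aif <- gen_aif_concentration(
    gamma_variate_params(3, 2.5, 1.2, 1), seq(0, 48, by = 0.5)
  )
  m <- curve_metrics(aif, baseline_n = 4)
  expect_equal(m$fwhm, oracle, tolerance = 0.5) # within one sample interval
})

test_that("recirculation adds a delayed tail without moving the first pass", {
  times <- seq(0, 48, by = 0.8)
  p0 <- gamma_variate_params(4, 2.5, 1.5, 3)
  p1 <- gamma_variate_params(4, 2.5, 1.5, 3,
    recirc_frac = 0.2, recirc_delay = 12
  )
  a0 <- gen_aif_concentration(p0, times)
  a1 <- gen_aif_concentration(p1, times)
  expect_equal(a0$value[times < 16], a1$value[times < 16], tolerance = 1e-6)
  expect_true(mean(a1$value[times > 20]) > mean(a0$value[times > 20]))
})

test_that("tissue forward model is linear in MBF and zero at zero flow", {
  aif <- fixture_aif()
  expect_true(all(
    gen_tissue_curve(aif, fermi_kinetics(0, 4, 0.3))$value == 0
  ))
  t1 <- gen_tissue_curve(aif, fermi_kinetics(1.7, 4, 0.3, 0.5))
  t2 <- gen_tissue_curve(aif, fermi_kinetics(3.4, 4, 0.3, 0.5))
  expect_equal(2 * t1$value, t2$value, tolerance = 1e-12)
  expect_equal(t1$value[1], 0)
  expect_lt(max(t1$value), max(aif$value))
})

test_that("tissue forward model agrees with a finer-grid quadrature", {
  aif <- fixture_aif(dt = 1) # heart rate 60
  kin <- fermi_kinetics(2.0, tau0 = 4, k = 0.3, delay = 0.5)
  coarse <- gen_tissue_curve(aif, kin, refine = 10L)
  fine <- gen_tissue_curve(aif, kin, refine = 100L)
  expect_lt(max(abs(coarse$value - fine$value)) / max(fine$value), 0.01)
})

test_that("subject simulation is reproducible and saturation is present", {
  s1 <- simulate_subject(cohort_config(), seed = 42)
  s2 <- simulate_subject(cohort_config(), seed = 42)
  expect_identical(s1$sat_aif$value, s2$sat_aif$value)
  expect_identical(s1$segment_kinetics, s2$segment_kinetics)
  s3 <- simulate_subject(cohort_config(), seed = 43)
  expect_false(identical(s1$sat_aif$value, s3$sat_aif$value))

  conv <- function(sig) {
    concentration_from_signal(
      sig, baseline_signal(sig), s1$acq$t1_blood, s1$acq$r1
    )
  }
  expect_lt(max(conv(s1$sat_aif)$value), max(conv(s1$ref_aif)$value))
  expect_lt(max(conv(s1$ref_aif)$value), max(s1$aif_true$value))
})

test_that("added signal noise has zero mean over many draws", {
  cfg <- cohort_config()
  noise <- unlist(lapply(1:30, function(i) {
    s <- simulate_subject(cfg, seed = 1000 + i)
    clean <- sr_signal(s$aif_true, s$acq$t1_blood, s$acq$ts_standard,
      gain = s$gain, r1 = s$acq$r1
    )
    s$sat_aif$value - clean$value
  }))
  se <- sd(noise) / sqrt(length(noise))
  expect_lt(abs(mean(noise)), 3 * se)
})

test_that("cohort splits have the right sizes and are disjoint", {
  expect_equal(
    unname(aifnet:::split_sizes(10, c(0.8, 0.1, 0.1))), c(8L, 1L, 1L)
  )
  co <- small_cohort()
  expect_length(co$train, 6)
  expect_length(co$val, 2)
  expect_length(co$test, 2)
  ids <- c(
    vapply(co$train, `[[`, "", "id"),
    vapply(co$val, `[[`, "", "id"),
    vapply(co$test, `[[`, "", "id")
  )
  expect_length(unique(ids), 10)

  co2 <- gen_cohort(cohort_config(
    n_subjects = 10,
    fractions = c(0.6, 0.2, 0.2), seed = 999
  ))
  expect_false(identical(
    co$train[[1]]$sat_aif$value, co2$train[[1]]$sat_aif$value
  ))
  expect_error(cohort_config(fractions = c(0.5, 0.2)), "summing to 1")
})

test_that("cohort directory round trip reconstructs subjects", {
  d <- withr::local_tempdir()
  co <- small_cohort()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_length(back$train, length(co$train))
  s0 <- co$test[[1]]
  s1 <- back$test[[which(vapply(back$test, `[[`, "", "id") == s0$id)]]
  expect_equal(s1$sat_aif$value, s0$sat_aif$value, tolerance = 1e-12)
  expect_equal(s1$segment_kinetics$mbf, s0$segment_kinetics$mbf,
    tolerance = 1e-12
  )
  expect_equal(s1$heart_rate, s0$heart_rate, tolerance = 1e-12)
  expect_equal(attr(s1$ref_aif, "ts"), 0.0235)
})
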