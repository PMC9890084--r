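# Saturation-recovery signal physics and concentration conversion.

test_that("post-contrast T1 follows the linear relaxation-rate model", {
  expect_equal(t1_post_contrast(0, 1.736), 1.736)
  expect_equal(t1_post_contrast(5, 1.736, 4.5), 1 / (1 / 1.736 + 22.5),
    tolerance = 1e-10
  )
  expect_equal(t1_post_contrast(1, 1.435, 4.5), 1 / (1 / 1.435 + 4.5),
    tolerance = 1e-10
  )
  # strictly decreasing in concentration
  cvals <- seq(0, 8, by = 0.5)
  expect_true(all(diff(t1_post_contrast(cvals, 1.736)) < 0))
  expect_error(t1_post_contrast(-1, 1.736), "concentration")
})

test_that("saturation-recovery signal matches the closed form and saturates", {
  cc <- conc_curve(0:5, c(0, 0, 0, 0, 5, 5))
  s_std <- sr_signal(cc, t1_0 = 1.736, ts = 0.100, gain = 1)
  expect_equal(s_std$value[1], 1 - exp(-0.100 / 1.736), tolerance = 1e-6)
  expect_equal(s_std$value[5], 1 - exp(-0.100 * (1 / 1.736 + 4.5 * 5)),
    tolerance = 1e-6
  )
  s_short <- sr_signal(cc, t1_0 = 1.736, ts = 0.0235, gain = 1)
  expect_equal(s_short$value[5], 1 - exp(-0.0235 * (1 / 1.736 + 4.5 * 5)),
    tolerance = 1e-6
  )

  # monotone increasing and concave in concentration
  grid <- conc_curve(seq_along(seq(0, 6, 0.25)), seq(0, 6, 0.25))
  sv <- sr_signal(grid, 1.736, 0.1)$value
  expect_true(all(diff(sv) > 0))
  expect_true(all(diff(diff(sv)) < 0))
})

test_that("relative-enhancement conversion is linear and shows saturation", {
  # converted concentration of the TS=100 ms signal of true C=5 mM
  cc <- conc_curve(1:8, c(0, 0, 0, 0, 5, 5, 5, 5))
  sig <- sr_signal(cc, 1.736, 0.100, gain = 1)
  conv <- concentration_from_signal(
    sig, baseline_signal(sig), 1.736, 4.5
  )
  enh <- (sig$value[5] - sig$value[1]) / sig$value[1]
  expect_equal(conv$value[5], enh / (4.5 * 1.736), tolerance = 1e-6)
  expect_equal(conv$value[5], 1.930, tolerance = 1e-3)
  # the short-TS reference still under-reads (residual saturation)
  sig_s <- sr_signal(cc, 1.736, 0.0235, gain = 1)
  conv_s <- concentration_from_signal(
    sig_s, baseline_signal(sig_s), 1.736, 4.5
  )
  expect_equal(conv_s$value[5], 3.857, tolerance = 1e-3)
  expect_lt(conv$value[5], conv_s$value[5])
  expect_lt(conv_s$value[5], 5)

  # no enhancement -> zero concentration
  flat <- signal_curve(1:6, rep(2, 6), ts = 0.1)
  expect_true(all(
    concentration_from_signal(flat, 2, 1.736)$value == 0
  ))
  expect_error(
    concentration_from_signal(flat, 0, 1.736),
    "positive blood-pool baseline"
  )
})

test_that("conversion is an affine map of the signal values", {
  withr::local_seed(11)
  for (i in 1:5) {
    v1 <- abs(rnorm(20, 10, 2))
    v2 <- abs(rnorm(20, 10, 2))
    a <- runif(1, 0.5, 2)
    s <- function(v) signal_curve(1:20, v, ts = 0.1)
    conv <- function(v) concentration_from_signal(s(v), 5, 1.736)$value
    # C(a*v1 + (1-a)*v2) == a*C(v1) + (1-a)*C(v2)
    expect_equal(
      conv(a * v1 + (1 - a) * v2),
      a * conv(v1) + (1 - a) * conv(v2),
      tolerance = 1e-12
    )
  }
})

test_that("short saturation times make the conversion exact in the limit", {
  true_c <- c(rep(0, 4), seq(0.1, 2, by = 0.1))
  cc <- conc_curve(seq_along(true_c), true_c)
  nz <- true_c > 0
  rel_err <- function(ts) {
    sig <- sr_signal(cc, 1.736, ts, gain = 7)
    est <- concentration_from_signal(
      sig, baseline_signal(sig), 1.736, 4.5
    )
    max(abs(est$value[nz] - true_c[nz]) / true_c[nz])
  }
  expect_lt(rel_err(0.001), 0.01)
  errs <- vapply(c(0.05, 0.02, 0.01, 0.005, 0.002, 0.001), rel_err, 0)
  expect_true(all(diff(errs) < 0))
})

# a bolus-like shape for ordering tests
gamma_variate_eval_test <- function(t) {
  u <- pmax(t, 0)
  4 * (u / 3)^2.5 * exp(2.5 - u / 1.2)
}

test_that("saturation ordering holds for converted curves", {
  cc <- conc_curve(0:20, c(rep(0, 4), gamma_variate_eval_test(0:16)))
  conv_at <- function(ts) {
    sig <- sr_signal(cc, 1.736, ts, gain = 3)
    concentration_from_signal(sig, baseline_signal(sig), 1.736)$value
  }
  c100 <- conv_at(0.100)
  c23 <- conv_at(0.0235)
  expect_true(all(c100 <= c23 + 1e-12))
  expect_true(all(c23 <= cc$value + 1e-12))
})

test_that("curve CSV round trip preserves values and acquisition context", {
  d <- withr::local_tempdir()
  sc <- signal_curve(seq(0, 9, 0.5), abs(sin(seq(0, 9, 0.5))) + 1,
    ts = 0.0235, baseline_n = 3L
  )
  p <- file.path(d, "aif.csv")
  write_curve(sc, p)
  back <- read_curve(p)
  expect_s3_class(back, "signal_curve")
  expect_equal(back$value, sc$value)
  expect_equal(attr(back, "ts"), 0.0235)
  expect_equal(attr(back, "baseline_n"), 3L)
})
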