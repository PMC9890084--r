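# Evaluation statistics against brute-force oracles.

test_that("NMSE matches its algebraic values", {
  expect_equal(nmse(c(1, 2, 3), c(1, 2, 3)), 0)
  ref <- c(4, 5, -2, 7)
  expect_equal(nmse(1.1 * ref, ref), 1, tolerance = 1e-12)
  expect_equal(nmse(-ref, ref), 400, tolerance = 1e-12)
  expect_error(nmse(1:3, rep(0, 3)), "all zero")
  expect_error(nmse(1:3, 1:4), "same length")
})

test_that("curve metrics on a symmetric triangle and a plateau", {
  tri <- conc_curve(0:10, c(0:5, 4:0) / 5)
  m <- curve_metrics(tri, baseline_n = 1)
  expect_equal(m$pv, 1)
  expect_equal(m$ttp, 5)
  expect_equal(m$fwhm, 5)
  # plateau: first time attaining the maximum
  plat <- conc_curve(0:6, c(0, 1, 3, 3, 3, 1, 0))
  expect_equal(curve_metrics(plat, baseline_n = 1)$ttp, 2)
  # monotone curve: no falling half-max crossing -> flagged
  mono <- conc_curve(0:5, c(0, 1, 2, 3, 4, 5))
  mm <- curve_metrics(mono, baseline_n = 1)
  expect_false(mm$fwhm_defined)
  expect_true(is.na(mm$fwhm))
})

test_that("curve metrics reproduce the gamma-variate fixture oracle", {
  aif <- fixture_aif(dt = 0.5)
  m <- curve_metrics(aif, baseline_n = 4)
  expect_equal(m$ttp, 6.0, tolerance = 0.5) # analytic mode t0 + alpha*beta
  f <- function(t) {
    u <- pmax(t - 3, 0)
    ifelse(t > 3, (u / 3)^2.5 * exp(2.5 - u / 1.2), 0)
  }
  expect_equal(m$fwhm, fwhm_oracle(f), tolerance = 0.5)
})

test_that("Bland-Altman agrees with a brute-force reimplementation", {
  expect_equal(bland_altman(1:5, 1:5)$bias, 0)
  ba0 <- bland_altman(1:5 + 0.5, 1:5)
  expect_equal(ba0$bias, 0.5)
  expect_equal(ba0$loa_low, 0.5)
  expect_equal(ba0$loa_high, 0.5)
  expect_equal(ba0$slope, 1)
  expect_equal(ba0$r2, 1)

  withr::local_seed(8)
  for (i in 1:5) {
    a <- rnorm(30)
    b <- rnorm(30)
    ba <- bland_altman(a, b)
    d <- a - b
    expect_equal(ba$bias, sum(d) / 30, tolerance = 1e-12)
    sd_d <- sqrt(sum((d - mean(d))^2) / 29)
    expect_equal(ba$loa_low, mean(d) - 1.96 * sd_d, tolerance = 1e-12)
    expect_equal(ba$loa_high, mean(d) + 1.96 * sd_d, tolerance = 1e-12)
    # OLS by hand
    beta1 <- sum((b - mean(b)) * (a - mean(a))) / sum((b - mean(b))^2)
    beta0 <- mean(a) - beta1 * mean(b)
    r2 <- 1 - sum((a - beta0 - beta1 * b)^2) / sum((a - mean(a))^2)
    expect_equal(ba$slope, beta1, tolerance = 1e-12)
    expect_equal(ba$intercept, beta0, tolerance = 1e-12)
    expect_equal(ba$r2, r2, tolerance = 1e-12)
    expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  }
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("cohort comparison reports median (IQR) and rank-sum p-values", {
  same <- compare_cohorts(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  sep <- compare_cohorts(1:10, 101:110)
  expect_lt(sep$p_value, 0.01)
  # exact rank-sum enumeration oracle for small disjoint samples
  expect_equal(sep$p_value,
    stats::wilcox.test(1:10, 101:110, exact = TRUE)$p.value,
    tolerance = 1e-12
  )
  m <- compare_cohorts(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(m$median_a, 3)
  expect_equal(m$iqr_a, 2)
  expect_error(compare_cohorts(numeric(0), 1:3), "non-empty")
})

test_that("diagnostic agreement equals the brute-force count", {
  a <- tibble::tibble(aha_id = 1:16, abnormal = rep(c(TRUE, FALSE), 8))
  expect_equal(diagnostic_agreement(a, a)$agreement_pct, 100)
  b <- a
  b$abnormal[16] <- !b$abnormal[16]
  expect_equal(diagnostic_agreement(a, b)$agreement_pct, 93.75)

  withr::local_seed(13)
  for (i in 1:5) {
    x <- tibble::tibble(
      id = rep(sprintf("P%02d", 1:4), each = 16),
      aha_id = rep(1:16, 4),
      abnormal = runif(64) < 0.3
    )
    y <- dplyr::mutate(x, abnormal = runif(64) < 0.3)
    expect_equal(
      diagnostic_agreement(x, y)$agreement_pct,
      100 * mean(x$abnormal == y$abnormal),
      tolerance = 1e-12
    )
  }
  mism <- tibble::tibble(aha_id = 1:15, abnormal = rep(TRUE, 15))
  expect_error(diagnostic_agreement(a, mism), "do not match")
})
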