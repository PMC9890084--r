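# Fermi-constrained deconvolution and diagnostic classification.

test_that("deconvolution inverts the forward model", {
  aif <- fixture_aif()
  kin <- fermi_kinetics(2.0, tau0 = 4, k = 0.3, delay = 0.5)
  tissue <- gen_tissue_curve(aif, kin)
  fit <- fermi_deconvolve(aif, tissue)
  expect_true(fit$converged)
  expect_equal(fit$mbf, 2.0, tolerance = 0.02)

  # linearity: scaled tissue -> scaled MBF
  t15 <- conc_curve(tissue$time_s, 1.5 * tissue$value)
  expect_equal(fermi_deconvolve(aif, t15)$mbf, 3.0, tolerance = 0.02 * 3)

  # zero tissue -> zero flow
  z <- conc_curve(aif$time_s, numeric(nrow(aif)))
  fit0 <- fermi_deconvolve(aif, z)
  expect_equal(fit0$mbf, 0)
  expect_true(fit0$converged)
})

test_that("MBF scales inversely with a rescaled AIF", {
  aif <- fixture_aif()
  tissue <- gen_tissue_curve(aif, fermi_kinetics(2.0, 4, 0.3, 0.5))
  aif2 <- conc_curve(aif$time_s, 2 * aif$value)
  expect_equal(fermi_deconvolve(aif2, tissue)$mbf, 1.0, tolerance = 0.02)
  # common rescaling of both leaves MBF unchanged
  t2 <- conc_curve(tissue$time_s, 2 * tissue$value)
  expect_equal(fermi_deconvolve(aif2, t2)$mbf, 2.0, tolerance = 0.02)
})

test_that("grid mismatch and short curves are rejected", {
  aif <- fixture_aif()
  other <- conc_curve(aif$time_s + 0.3, aif$value)
  expect_error(fermi_deconvolve(aif, other), "time grid")
  short <- conc_curve(0:9, c(0, 0, 1, 3, 5, 4, 3, 2, 1, 1))
  expect_error(fermi_deconvolve(short, short), "16 samples")
})

test_that("pixelwise quantification is per-pixel independent", {
  aif <- fixture_aif()
  t1 <- gen_tissue_curve(aif, fermi_kinetics(1.0, 3, 0.3, 0))$value
  t3 <- gen_tissue_curve(aif, fermi_kinetics(3.0, 3, 0.3, 0))$value
  m <- cbind(t1, t1, t3, t1)
  res <- quantify_pixelwise(aif, m)
  expect_equal(res$mbf, c(1, 1, 3, 1), tolerance = 0.02 * 3)
  # permuting pixels permutes outputs
  perm <- c(3, 1, 4, 2)
  res_p <- quantify_pixelwise(aif, m[, perm])
  expect_equal(res_p$mbf, res$mbf[perm], tolerance = 1e-8)
  # identical curves give identical values
  res_s <- quantify_pixelwise(aif, cbind(t1, t1))
  expect_equal(res_s$mbf[1], res_s$mbf[2], tolerance = 1e-10)
})

test_that("segment classification uses a strict threshold", {
  expect_true(classify_segment(1.0))
  expect_false(classify_segment(2.0))
  expect_false(classify_segment(1.35)) # boundary is normal
  expect_error(classify_segment(-0.1), "mbf")
})

test_that("vessel diagnosis averages the two lowest territory segments", {
  mbf <- c(
    2.0, 1.2, 3, 3, 3, 3, 1.3, 3.0, 3, 3, 3, 3, 2.5, 2.8, 3, 3
  )
  seg <- tibble::tibble(aha_id = 1:16, mbf = mbf)
  v <- classify_vessel(seg)
  lad <- v[v$territory == "LAD", ]
  # LAD segments {1,2,7,8,13,14} -> MBFs {2.0,1.2,1.3,3.0,2.5,2.8}
  expect_equal(lad$mbf_two_lowest_mean, mean(c(1.2, 1.3)))
  expect_true(lad$abnormal)
  expect_false(v$abnormal[v$territory == "RCA"])

  all3 <- classify_vessel(tibble::tibble(aha_id = 1:16, mbf = rep(3, 16)))
  expect_false(any(all3$abnormal))
  expect_equal(nrow(all3), 3)

  # tie at the minimum: both tied segments are used
  tie <- rep(3, 16)
  tie[c(1, 2)] <- 1.0
  vt <- classify_vessel(tibble::tibble(aha_id = 1:16, mbf = tie))
  expect_equal(vt$mbf_two_lowest_mean[vt$territory == "LAD"], 1.0)

  expect_error(
    classify_vessel(tibble::tibble(aha_id = 1:15, mbf = rep(3, 15))),
    "16"
  )
})

test_that("territory map covers all 16 segments exactly once", {
  tm <- aha_territories()
  expect_equal(sort(tm$aha_id), 1:16)
  expect_equal(sum(tm$territory == "LAD"), 6)
  expect_equal(sum(tm$territory == "RCA"), 5)
  expect_equal(sum(tm$territory == "LCX"), 5)
})

test_that("ground-truth recovery holds across a whole synthetic subject", {
  s <- one_subject()
  res <- quantify_segments(s$aif_true, s$tissue_true)
  expect_true(all(res$converged))
  rel <- abs(res$mbf - s$segment_kinetics$mbf) / s$segment_kinetics$mbf
  expect_lt(median(rel), 0.03)
  expect_equal(
    res$abnormal, s$segment_kinetics$mbf < 1.35
  )
})
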