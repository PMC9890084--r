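# Preprocessing: arrival detection, cropping, length fixing,
# normalization, blood-pool ROI extraction.

test_that("arrival detection finds a constructed step and rejects flat curves", {
  sc <- signal_curve(0:7, c(1, 1, 1, 1, 1, 8, 20, 30), ts = 0.1)
  # baseline frames 1..4 are flat; frame 6 (value 8) is the first to exceed
  expect_equal(detect_arrival(sc, n_base = 4, k_sigma = 5), 6L)
  flat <- signal_curve(0:7, rep(2, 8), ts = 0.1)
  expect_error(detect_arrival(flat), "arrival not found")
  expect_error(detect_arrival(sc, n_base = 1), "n_base")
})

test_that("arrival detection tolerates noise within one frame", {
  cfg <- cohort_config()
  hits <- vapply(1:100, function(i) {
    s <- simulate_subject(cfg, seed = 5000 + i)
    arr <- detect_arrival(s$sat_aif)
    # truth: first frame strictly after the drawn arrival time
    truth <- which(s$sat_aif$time_s > s$gamma$t0)[1]
    abs(arr - truth) <= 1
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("pre-contrast crop keeps four beats and clamps at the start", {
  sc <- signal_curve(0:19, c(rep(1, 10), 8, 20, 15, rep(6, 7)), ts = 0.1)
  out <- crop_pre_contrast(sc, arrival_index = 11, n_pre = 4)
  expect_equal(out$value[1], sc$value[7])
  expect_equal(out$time_s[1], 0)
  clamped <- crop_pre_contrast(sc, arrival_index = 2, n_pre = 4)
  expect_equal(nrow(clamped), nrow(sc))
  noop <- crop_pre_contrast(sc, arrival_index = 5, n_pre = 4)
  expect_equal(noop$value, sc$value)
})

test_that("fix_length truncates, pads with the last value, and is idempotent", {
  expect_equal(fix_length(c(1, 2, 3)), c(1, 2, 3, rep(3, 61)))
  expect_equal(fix_length(seq_len(70)), seq_len(64))
  x <- rnorm(64)
  expect_identical(fix_length(x), x)
  expect_identical(fix_length(fix_length(x)), fix_length(x))
  expect_error(fix_length(numeric(0)), "non-empty")
})

test_that("pair normalization divides by the saturated max and inverts exactly", {
  sat <- c(rep(2, 10), seq(2, 200, length.out = 44), seq(180, 30, length.out = 10))
  unsat <- 1.5 * sat
  pair <- normalize_pair(sat, unsat, dt = 0.8)
  expect_equal(pair$scale, 200)
  expect_equal(max(pair$sat), 1)
  expect_equal(max(pair$unsat), 1.5)
  back <- unnormalize_pair(pair)
  expect_identical(back$sat, sat)
  expect_identical(back$unsat, unsat)
  expect_error(normalize_pair(rep(0, 64), rep(0, 64)), "positive")

  # property: round trip on random curves
  withr::local_seed(2)
  for (i in 1:10) {
    s <- abs(rnorm(64, 10, 5)) + 0.1
    u <- abs(rnorm(64, 15, 5)) + 0.1
    expect_identical(unnormalize_pair(normalize_pair(s, u)), list(sat = s, unsat = u))
  }
})

test_that("blood-pool ROI averages only supra-75th-percentile pixels", {
  t <- 0:9
  mk <- function(peak) c(rep(1, 4), 1 + peak * c(0.5, 1, 0.8, 0.5, 0.3, 0.2))
  px <- cbind(mk(1), mk(2), mk(3), mk(10))
  # peaks 2,3,4,11 -> 75th percentile of peak values isolates the brightest
  roi <- extract_aif_roi(px, t, rep(TRUE, 4))
  expect_equal(roi$value, px[, 4])

  # 8 distinct pixels -> exactly the top-2 averaged
  px8 <- sapply(1:8, function(i) mk(i))
  roi8 <- extract_aif_roi(px8, t, rep(TRUE, 8))
  expect_equal(roi8$value, rowMeans(px8[, 7:8]))

  # identical pixels -> any single curve
  same <- sapply(1:6, function(i) mk(2))
  expect_equal(extract_aif_roi(same, t, rep(TRUE, 6))$value, mk(2))

  # selecting bright pixels cannot lower the peak
  expect_gte(max(roi8$value), max(rowMeans(px8)))
  expect_error(extract_aif_roi(px, t, rep(FALSE, 4)), "empty")
})

test_that("the quantile rule uses linear interpolation with strict exceedance", {
  # peaks 1,2,3,10: type-7 75th percentile is 4.75, so only peak-10 passes
  expect_equal(
    stats::quantile(c(1, 2, 3, 10), 0.75, type = 7, names = FALSE), 4.75
  )
  t <- 0:5
  px <- sapply(c(1, 2, 3, 10), function(p) c(1, 1, 1, 1, p, p / 2))
  roi <- extract_aif_roi(px, t, rep(TRUE, 4))
  expect_equal(roi$value, px[, 4])
})

test_that("prep_aif_pair composes the chain and records bookkeeping", {
  s <- one_subject()
  pair <- prep_aif_pair(s$sat_aif, s$ref_aif)
  expect_s3_class(pair, "aif_pair")
  expect_length(pair$sat, 64)
  expect_equal(max(pair$sat), 1, tolerance = 1e-12)
  expect_gt(max(pair$unsat), 1) # reference exceeds saturated peak
  expect_equal(pair$dt, 60 / s$heart_rate, tolerance = 1e-9)
})

test_that("pair batches round-trip through per-pair CSV files", {
  d <- withr::local_tempdir()
  co <- small_cohort()
  pairs <- cohort_pairs(co$train[1:3])
  write_pairs(pairs, d)
  back <- read_pairs(d)
  expect_length(back, 3)
  expect_equal(back[[2]]$sat, pairs[[2]]$sat, tolerance = 1e-12)
  expect_equal(back[[2]]$scale, pairs[[2]]$scale, tolerance = 1e-12)
})
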