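test_that("extract_xic applies an inclusive ppm window per scan", {
  run <- run_data("r", times = c(1, 2, 3), scans = list(
    cbind(mz = 500.000, intensity = 1000),
    cbind(mz = 500.010, intensity = 800),          # 20 ppm away: outside
    cbind(mz = c(499.9996, 500.0004), intensity = c(10, 20))))
  x <- extract_xic(run, 500.000, ppm_window = 10)  # half-window 0.005 Th
  expect_s3_class(x, "xic")
  expect_equal(x$intensities, c(1000, 0, 30))
  expect_equal(x$times, run$times)
})

test_that("first_isotope_mz adds one neutron spacing over the charge", {
  expect_equal(first_isotope_mz(500, 1), 501.0033548)
  expect_equal(first_isotope_mz(500, 2), 500.5016774)
  expect_equal(first_isotope_mz(400, 3), 400 + 1.0033548 / 3)
  expect_error(first_isotope_mz(500, 0), "charge")
})

test_that("estimate_noise is the median level with a MAD-based sigma", {
  expect_equal(unclass(estimate_noise(make_xic(1:10, rep(5, 10)))),
               list(level = 5, sigma = 0))
  expect_equal(unclass(estimate_noise(make_xic(1:10, rep(0, 10)))),
               list(level = 0, sigma = 0))
  # baseline noise plus sparse high peaks: the regime the estimator targets
  set.seed(7)
  y <- rnorm(10000, mean = 100, sd = 12)
  peaks <- sample(10000, 500)
  y[peaks] <- y[peaks] + runif(500, 500, 5000)
  ns <- estimate_noise(make_xic(seq_len(10000), y))
  expect_lt(abs(ns$level - 100) / 100, 0.02)
  expect_lt(abs(ns$sigma - 12) / 12, 0.10)
})

test_that("detect_peak_intervals thresholds at level + 3 sigma", {
  ns <- structure(list(level = 0, sigma = 0), class = "noise_estimate")
  expect_equal(detect_peak_intervals(make_xic(1:50, rep(0, 50)), ns), list())

  t <- seq(0, 100, by = 1)
  y <- 100 * exp(-(t - 40)^2 / (2 * 4^2))
  iv <- detect_peak_intervals(make_xic(t, y), ns)
  expect_length(iv, 1L)
  expect_equal(iv[[1]]$apex_time, t[which.max(y)])
  expect_equal(iv[[1]]$apex_intensity, max(y))

  y2 <- y + 60 * exp(-(t - 80)^2 / (2 * 3^2))
  iv2 <- detect_peak_intervals(make_xic(t, y2), ns, max_n = 1)
  expect_length(iv2, 1L)
  expect_equal(iv2[[1]]$apex_time, 40)  # higher apex wins

  # brute-force oracle: interval bounds are exactly the threshold crossings
  ns2 <- structure(list(level = 10, sigma = 5), class = "noise_estimate")
  iv3 <- detect_peak_intervals(make_xic(t, y2), ns2)
  thr <- 10 + 3 * 5
  for (v in iv3) {
    expect_true(all(v$intensities > thr))
    expect_equal(max(v$intensities), v$apex_intensity)
  }
})

test_that("interval properties hold across random traces", {
  set.seed(31)
  for (rep in 1:25) {
    t <- seq(0, 200, by = 1)
    y <- pmax(rnorm(length(t), 10, 3), 0)
    for (k in seq_len(sample(1:4, 1)))
      y <- y + runif(1, 50, 500) *
        exp(-(t - runif(1, 20, 180))^2 / (2 * runif(1, 2, 6)^2))
    x <- make_xic(t, y)
    ns <- estimate_noise(x)
    iv <- detect_peak_intervals(x, ns, max_n = 10, min_points = 3)
    thr <- ns$level + 3 * ns$sigma
    if (length(iv) == 0) next
    # every interval exceeds the threshold and they are pairwise disjoint
    expect_true(all(vapply(iv, function(v) max(v$intensities) > thr,
                           logical(1))))
    starts <- vapply(iv, `[[`, numeric(1), "start_time")
    ends <- vapply(iv, `[[`, numeric(1), "end_time")
    expect_true(all(starts[-1] > ends[-length(ends)]))
    expect_true(all(vapply(iv, function(v) length(v$times) >= 3, logical(1))))
    # scale invariance: scaling the trace and the noise leaves bounds fixed
    x2 <- make_xic(t, y * 7.5)
    ns2 <- structure(list(level = ns$level * 7.5, sigma = ns$sigma * 7.5),
                     class = "noise_estimate")
    iv2 <- detect_peak_intervals(x2, ns2, max_n = 10, min_points = 3)
    expect_equal(vapply(iv2, `[[`, numeric(1), "start_time"), starts)
    expect_equal(vapply(iv2, `[[`, numeric(1), "end_time"), ends)
  }
})

test_that("locate_feature selects by containment, then nearest apex", {
  iv <- list(make_iv(90:110, c(1:11, 10:1) * 10),
             make_iv(200:220, c(1:11, 10:1) * 5))
  expect_equal(locate_feature(iv, 100)$start_time, 90)
  expect_equal(locate_feature(iv, 115, rt_tolerance = 60)$start_time, 90)
  expect_error(locate_feature(iv, 500), class = "feature_not_found")
  expect_error(locate_feature(list(), 100), class = "feature_not_found")
})

test_that("candidate lists contain the planted peak at high SNR", {
  hits <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_peptides = 6, decoys_per_peptide = 1,
                      decoy_offset_range = c(25, 50), run_length = 500,
                      noise_level = 10, noise_sigma = 3)
    ex <- simulate_runs(cfg, seed = seed)
    tr <- ex$truth[ex$truth$run_id == "run02", ]
    ctl <- mbr_control()
    ok <- vapply(seq_len(nrow(tr)), function(i) {
      x <- mbralign:::detection_xic(ex$runs[[2]], tr$mz_mono[i],
                                    tr$charge[i], ctl)
      cv <- candidate_features(x)
      any(vapply(cv, function(v)
        v$start_time <= tr$apex_time[i] && tr$apex_time[i] <= v$end_time,
        logical(1)))
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_gte(mean(hits), 0.99)
})
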