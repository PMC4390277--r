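test_that("baseline correction subtracts the window mean", {
  flat <- structure(list(cycle = 1:40, fluorescence = rep(5, 40)),
                    class = "amplification_curve")
  expect_equal(baseline_correct(flat, c(3, 15))$fluorescence, rep(0, 40))
  ramp <- structure(list(cycle = 1:40, fluorescence = as.numeric(1:40)),
                    class = "amplification_curve")
  expect_equal(baseline_correct(ramp, c(1, 3))$fluorescence, 1:40 - 2)
  expect_error(baseline_correct(flat, c(0, 15)), "window")
  # removing a known baseline recovers the closed-form signal when the
  # window holds negligible amplification signal
  p <- curve_params(1e-13, efficiency = 1, xmax = 1e9, baseline = 0.7,
                    noise_sd = 0)
  cv <- baseline_correct(simulate_curve(p), c(3, 15))
  expect_lt(max(abs(cv$fluorescence[30:36] -
                      amplification_signal(30:36, p))), 1e-9)
})

test_that("fixed-threshold Ct has the doubling-curve closed form", {
  cv <- ideal_curve()
  cc <- call_ct_fixed(cv, 0.03)
  expect_equal(cc$status, "EXPRESSED")
  expect_equal(cc$ct, log2(30), tolerance = 1e-6)
  expect_equal(call_ct_fixed(cv, 0.5)$ct - cc$ct, log2(0.5 / 0.03),
               tolerance = 1e-6)
  flat <- structure(list(cycle = 1:40, fluorescence = rep(0.001, 40)),
                    class = "amplification_curve")
  expect_equal(call_ct_fixed(flat, 0.03)$status, "NOT_EXPRESSED")
  expect_error(call_ct_fixed(cv, -1), "threshold")
})

test_that("threshold-shift identity holds for any efficiency", {
  for (e in c(0.6, 0.8, 1)) {
    cv <- ideal_curve(x0 = 1e-6, efficiency = e)
    t1 <- 0.01; t2 <- 0.2
    d <- call_ct_fixed(cv, t2)$ct - call_ct_fixed(cv, t1)$ct
    expect_equal(d, log(t2 / t1) / log(1 + e), tolerance = 1e-4)
  }
})

test_that("Ct is monotone in threshold and in starting amount", {
  cv <- ideal_curve()
  thr <- c(0.01, 0.03, 0.05, 0.5)
  cts <- vapply(thr, function(t) call_ct_fixed(cv, t)$ct, numeric(1))
  expect_true(all(diff(cts) > 0))
  # halving x0 at E = 1 delays Ct by exactly one cycle
  cv2 <- ideal_curve(x0 = 0.0005)
  expect_equal(call_ct_fixed(cv2, 0.03)$ct - call_ct_fixed(cv, 0.03)$ct,
               1, tolerance = 1e-9)
  # any threshold above the curve maximum is NOT_EXPRESSED
  expect_equal(call_ct_fixed(cv, max(cv$fluorescence) * 2)$status,
               "NOT_EXPRESSED")
})

test_that("a noise spike below a sustained crossing is not called", {
  f <- rep(0.001, 40)
  f[10] <- 0.05           # single-point artifact
  f[25:40] <- 0.04 * 2^(0:15)  # real sustained crossing
  cv <- structure(list(cycle = 1:40, fluorescence = f),
                  class = "amplification_curve")
  expect_gt(call_ct_fixed(cv, 0.03)$ct, 24)
})

test_that("auto threshold is internally consistent with fixed calling", {
  cv <- simulate_curve(curve_params(1e-4, efficiency = 0.9, xmax = 1,
                                    baseline = 0, noise_sd = 0))
  res <- call_ct_auto(list(cv))
  expect_false(res$flagged)
  expect_gt(res$threshold, 0)
  cc <- call_ct_fixed(cv, res$threshold)
  expect_equal(res$calls[[1]]$ct, cc$ct, tolerance = 1e-6)
  # identical curves get identical calls
  res2 <- call_ct_auto(list(cv, cv))
  expect_equal(res2$calls[[1]]$ct, res2$calls[[2]]$ct)
  # all-flat plate is flagged, every call NOT_EXPRESSED
  flat <- structure(list(cycle = 1:40, fluorescence = rep(1e-6, 40)),
                    class = "amplification_curve")
  resf <- call_ct_auto(list(flat))
  expect_true(resf$flagged)
  expect_equal(resf$calls[[1]]$status, "NOT_EXPRESSED")
})

test_that("auto and fixed Ct differ by the log2 threshold ratio", {
  # deep-exponential doubling curves: both thresholds inside the phase
  curves <- lapply(c(1e-4, 2e-5, 5e-6), ideal_curve, efficiency = 1)
  res <- call_ct_auto(curves)
  for (k in seq_along(curves)) {
    d <- res$calls[[k]]$ct - call_ct_fixed(curves[[k]], 0.03)$ct
    expect_equal(d, log2(res$threshold / 0.03), tolerance = 1e-3)
  }
})

test_that("table-level calling matches the analytic fast path", {
  cfg <- small_config(13, duplicates = 2L, n = 4L, run_sd = 0.6)
  # push Ct values past the baseline window so its correction stays clean
  cfg$targets$abundance_mean <- c(30, 28, 26)
  cfg$curve <- curve_params(1e-6, efficiency = 1, xmax = 3,
                            baseline = 0.05, noise_sd = 0)
  sim <- simulate_experiment(cfg)
  called <- call_ct_table(sim$curves, threshold = 0.03)
  fast <- simulate_ct_table(cfg, threshold = 0.03)$ct
  key <- function(d) paste(d$sample, d$target, d$operator, d$replicate)
  mi <- match(key(called), key(fast))
  both <- !is.na(called$ct) & !is.na(fast$ct[mi])
  expect_gt(mean(both), 0.95)
  dev <- abs(called$ct[both] - fast$ct[mi][both])
  # early-Ct wells leak a little signal into the baseline window, which
  # shifts the corrected crossing slightly; the bulk agrees tightly
  expect_lt(median(dev), 0.02)
  expect_lt(max(dev), 0.1)
})
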