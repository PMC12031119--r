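fs <- 20

test_that("autocorrelation finds the breathing period", {
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  expect_equal(autocorr_rate(sin(2 * pi * 0.25 * t), fs), 15, tolerance = 1e-3)
  # 12 BPM with noise (SNR ~ 10 dB)
  set.seed(5)
  x <- sin(2 * pi * 0.2 * t) + 0.3 * rnorm(length(t))
  expect_equal(autocorr_rate(x, fs), 12, tolerance = 0.5 / 12)
  # white noise: undefined in the clear majority of draws
  na_count <- sum(vapply(1:30, function(s) {
    set.seed(s); is.na(autocorr_rate(rnorm(1200), fs))
  }, TRUE))
  expect_gte(na_count, 28)
  expect_true(is.na(autocorr_rate(rep(1, 1200), fs)))
})

test_that("sym4 filters are orthonormal and the SWT localizes QRS energy", {
  lo <- radarvitals:::SYM4_DEC_LO
  expect_equal(sum(lo), sqrt(2), tolerance = 1e-12)
  expect_equal(sum(lo^2), 1, tolerance = 1e-12)
  expect_equal(sum(lo * radarvitals:::SYM4_DEC_HI), 0, tolerance = 1e-12)
})

test_that("ECG heart rate recovers generator truth at 60 and 180 BPM", {
  seg <- body_segment(0.5, heartbeat = list(rate_bpm = 60, amp_var = 0))
  segb <- body_segment(1.0, breathing = list(rate_bpm = 12))
  spec <- scene_spec(list(seg, segb), duration = 60, noise_sigma = 0, seed = 3)
  ecg <- make_reference_streams(spec)$ecg
  fse <- 1 / diff(ecg$time_s[1:2])
  expect_equal(ecg_heart_rate(ecg$value, fse), 60, tolerance = 1 / 60)
  seg180 <- body_segment(0.5, heartbeat = list(rate_bpm = 180, amp_var = 0))
  spec2 <- scene_spec(list(seg180, segb), duration = 60, noise_sigma = 0, seed = 3)
  ecg2 <- make_reference_streams(spec2)$ecg
  expect_equal(ecg_heart_rate(ecg2$value, fse), 180, tolerance = 2 / 180)
  expect_true(is.na(ecg_heart_rate(rep(0, 6000), 100)))
})

test_that("radar heart rate recovers a clean 70 BPM pulse phase", {
  x <- band_filter(pulse_window(70, dur = 60, noise = 0.01, seed = 2),
                   "heartbeat", fs = fs)
  expect_equal(radar_heart_rate(x, fs), 70, tolerance = 1 / 70)
  # breathing leakage before the band-pass does not move the rate
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  leak <- pulse_window(70, dur = 60, noise = 0.01, seed = 2) +
    2.5 * sin(2 * pi * 0.25 * t)
  xl <- band_filter(leak, "heartbeat", fs = fs)
  expect_equal(radar_heart_rate(xl, fs), 70, tolerance = 1.5 / 70)
  # noise-only: undefined in most draws
  nas <- sum(vapply(1:20, function(s) {
    set.seed(s)
    is.na(radar_heart_rate(band_filter(0.05 * rnorm(1200), "heartbeat",
                                       fs = fs), fs))
  }, TRUE))
  expect_gte(nas, 15)
})

test_that("median aggregation is robust and bounded by the per-bin extremes", {
  expect_equal(aggregate_bins(c(15, 15, 16)), 15)
  expect_equal(aggregate_bins(15), 15)
  expect_equal(aggregate_bins(c(14, 15, 40)), 15)
  expect_true(is.na(aggregate_bins(c(NA_real_, NA_real_))))
  set.seed(1)
  for (i in 1:20) {
    r <- runif(sample(1:7, 1), 10, 25)
    a <- aggregate_bins(r)
    expect_gte(a, min(r)); expect_lte(a, max(r))
  }
})

test_that("error summary reproduces the MAE/MAPE arithmetic", {
  es <- error_summary(c(10, 12, 14), c(11, 12, 13))
  expect_equal(es$mae, 2 / 3, tolerance = 1e-9)
  expect_equal(es$mape, 100 * (1 / 10 + 0 + 1 / 14) / 3, tolerance = 1e-9)
  expect_equal(es$mape, 5.714, tolerance = 1e-3)
  expect_equal(es$pct_within_1bpm, 100)
  id <- error_summary(c(12, 14), c(12, 14))
  expect_equal(id$mae, 0); expect_equal(id$mape, 0)
  expect_equal(id$pct_within_1bpm, 100)
  # constant offset: sign convention is reference - radar
  off <- error_summary(c(10, 12), c(11, 13))
  expect_equal(off$mae, 1)
  expect_equal(off$mean_diff, -1)
  expect_equal(off$loa_lower, -1); expect_equal(off$loa_upper, -1)
  expect_error(error_summary(NA_real_, 5), "no windows")
})

test_that("MAPE is invariant to common rescaling; MAE bounded by max diff", {
  set.seed(8)
  a <- runif(20, 10, 20); b <- a + rnorm(20, sd = 0.5)
  e1 <- error_summary(a, b); e2 <- error_summary(3 * a, 3 * b)
  expect_equal(e1$mape, e2$mape, tolerance = 1e-9)
  expect_lte(e1$mae, max(abs(a - b)))
})
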