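dev <- device_config()

make_tone_cube <- function(bins, amps, dev, nf = 2, nc = 2) {
  ns <- dev$n_fast_samples
  ts <- (seq_len(ns) - 1) / dev$adc_rate
  sig <- rep(0+0i, ns)
  for (k in seq_along(bins)) {
    df <- dev$mu * 2 * (bins[k] * dev$delta_r) / 299792458
    sig <- sig + amps[k] * exp(2i * pi * df * ts)
  }
  cube <- array(0+0i, dim = c(nf, nc, ns))
  for (f in seq_len(nf)) for (c in seq_len(nc)) cube[f, c, ] <- sig
  cube
}

test_that("range FFT peaks at the tone's bin and zero maps to zero", {
  cube <- make_tone_cube(12, 1, dev)
  m <- range_fft(cube, dev)
  expect_equal(which.max(Mod(m$data[, 1])) - 1L, 12L)
  z <- range_fft(array(0+0i, dim = c(1, 2, dev$n_fast_samples)), dev)
  expect_true(all(Mod(z$data) == 0))
  bad <- array(NA_complex_, dim = c(1, 1, 8))
  expect_error(range_fft(bad, dev), "non-finite")
})

test_that("two separated tones resolve with Hanning leakage below -30 dB", {
  cube <- make_tone_cube(c(10, 30), c(1, 1), dev)
  m <- range_fft(cube, dev)
  mags <- Mod(m$data[, 1])
  expect_equal(sort(order(mags, decreasing = TRUE)[1:2]) - 1L, c(10L, 30L))
  # oracle: direct DFT of the windowed signal at a far-away bin
  peak <- max(mags)
  far <- mags[setdiff(seq_along(mags), c(10, 11, 12, 30, 31, 32))]
  expect_lt(max(far) / peak, 10^(-30 / 20))
})

test_that("chirp median is the identity on identical chirps and robust to outliers", {
  dev2 <- device_config(chirps_per_frame = 12L)
  vals <- complex(modulus = 2, argument = 0.10)
  data <- matrix(rep(vals, 12), nrow = 1)
  m <- range_time_matrix(data, (0:11) * dev2$chirp_interval, 0.5, dev2, "chirp")
  out <- chirp_median(m)
  expect_equal(out$data[1, 1], vals)
  # 11 chirps at phase 0.10, 1 outlier at 3.0 -> median 0.10
  data2 <- matrix(complex(modulus = 1, argument = c(rep(0.10, 11), 3.0)),
                  nrow = 1)
  m2 <- range_time_matrix(data2, (0:11) * dev2$chirp_interval, 0.5, dev2, "chirp")
  expect_equal(Arg(chirp_median(m2)$data[1, 1]), 0.10, tolerance = 1e-9)
})

test_that("chirp median near the +/-pi cut does not straddle branches", {
  dev2 <- device_config()
  ph <- pi - 0.05 + c(rep(0, 6), rep(0.1, 6))  # phases wrap past +pi
  data <- matrix(complex(modulus = 1, argument = ph), nrow = 1)
  m <- range_time_matrix(data, (0:11) * dev2$chirp_interval, 0.5, dev2, "chirp")
  med <- Arg(chirp_median(m)$data[1, 1])
  expect_equal(abs(med), pi - 0.0, tolerance = 0.1)
})

test_that("chirp median reduces phase noise (Monte-Carlo, asymptotic pi*s^2/2n)", {
  set.seed(99)
  nf <- 5000
  sigma <- 0.1
  ph <- matrix(rnorm(nf * 12, sd = sigma), nrow = 1)
  data <- matrix(complex(modulus = 1, argument = ph), nrow = 1)
  dev2 <- device_config()
  m <- range_time_matrix(data, (seq_len(nf * 12) - 1) * dev2$chirp_interval,
                         0.5, dev2, "chirp")
  out <- chirp_median(m)
  s <- sd(Arg(out$data[1, ]))
  expect_lt(s, 0.5 * sigma)
  expect_equal(s, sqrt(pi / 24) * sigma, tolerance = 0.1)
})

test_that("incomplete final frames are dropped with a message", {
  dev2 <- device_config()
  data <- matrix(complex(modulus = 1, argument = 0), nrow = 1, ncol = 30)
  m <- range_time_matrix(data, (0:29) * dev2$chirp_interval, 0.5, dev2, "chirp")
  expect_message(out <- chirp_median(m), "incomplete final frame")
  expect_equal(ncol(out$data), 2L)
})

test_that("phase extraction unwraps ramps and inverts displacement", {
  th <- seq(0, 4 * pi, length.out = 100)
  dev2 <- device_config()
  data <- matrix(exp(1i * th), nrow = 1)
  m <- range_time_matrix(data, (0:99) * 0.05, 0.5, dev2, "frame")
  p <- extract_phase(m, 0L)
  expect_equal(p$values[100], 4 * pi, tolerance = 1e-9)
  expect_true(all(abs(diff(p$values)) < pi))
  # constant phase -> zero displacement
  mc <- range_time_matrix(matrix(rep(1+0i, 50), 1), (0:49) * 0.05, 0.5,
                          dev2, "frame")
  d <- phase_to_displacement(extract_phase(mc, 0L), dev2$lambda_c,
                             relative = TRUE)
  expect_true(all(d == 0))
})

test_that("a 1 mm sinusoid at 60 GHz appears as a ~2.513 rad phase swing", {
  dev2 <- device_config()
  t <- seq(0, 10, by = 0.05)
  d <- 1e-3 * sin(2 * pi * 0.25 * t)
  data <- matrix(exp(1i * 4 * pi * d / dev2$lambda_c), nrow = 1)
  m <- range_time_matrix(data, t, 0.5, dev2, "frame")
  p <- extract_phase(m, 0L)
  expect_equal(max(p$values) - min(p$values), 2 * 2.513, tolerance = 0.01)
  # round trip to displacement
  back <- phase_to_displacement(p, dev2$lambda_c)
  expect_lt(max(abs(back - d)), 1e-9)
})

test_that("phase_to_displacement obeys the Eq.-6 inverse", {
  expect_equal(phase_to_displacement(0, 5e-3), 0)
  expect_equal(phase_to_displacement(4 * pi, 5e-3), 5e-3)
})

test_that("bin restriction keeps 0.4-3 m and rejects bad limits", {
  dev2 <- device_config()  # delta_r = 5 cm, 100 bins: 0-4.95 m
  nb <- 100
  data <- matrix(rep(1+0i, nb * 3), nrow = nb)
  m <- range_time_matrix(data, (0:2) * 0.05, (0:(nb - 1)) * dev2$delta_r,
                         dev2, "frame")
  r <- restrict_bins(m)
  # direct enumeration with the exact resolution c/(2B) = 4.9965 cm: the
  # nominal "bin 8" center is 0.3997 m, just below the 40 cm cut
  want <- which((0:(nb - 1)) * dev2$delta_r >= 0.4 &
                (0:(nb - 1)) * dev2$delta_r <= 3.0) - 1L
  expect_equal(r$bin_index, want)
  expect_equal(want, 9:60)
  expect_equal(nrow(r$data), 52L)
  r2 <- restrict_bins(m, min_m = 0)
  expect_equal(r2$bin_index[1], 0L)
  expect_error(restrict_bins(m, 2, 1), "max_m")
  expect_error(restrict_bins(m, 90, 99), "no bins remain")
})

test_that("range FFT energy scales linearly with input amplitude", {
  cube1 <- make_tone_cube(10, 1, dev)
  cube3 <- make_tone_cube(10, 3, dev)
  e1 <- sum(Mod(range_fft(cube1, dev)$data[, 1])^2)
  e3 <- sum(Mod(range_fft(cube3, dev)$data[, 1])^2)
  expect_equal(e3 / e1, 9, tolerance = 1e-6)
})
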