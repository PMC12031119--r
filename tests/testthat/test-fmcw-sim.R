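dev <- device_config()

test_that("displacement field places a sinusoid in the right bin", {
  spec <- scene_spec(list(body_segment(1.0, breathing = list(
    rate_bpm = 15, amplitude_m = 1e-3, harmonics = c(0, 0),
    depth_var = 0))), duration = 4, noise_sigma = 0, seed = 1)
  f <- displacement_field(spec, dev)
  b <- round(1.0 / dev$delta_r) + 1
  expect_equal(max(abs(f[b, ])), 1e-3, tolerance = 0.01)
  expect_true(all(f[-b, ] == 0))
  # period 4 s at 15 BPM: the series returns near its start value
  expect_lt(abs(f[b, 1] - f[b, ncol(f)]), 1e-4)
})

test_that("empty scene gives an all-zero field", {
  spec <- scene_spec(list(), duration = 2, noise_sigma = 0)
  f <- displacement_field(spec, dev)
  expect_true(all(f == 0))
})

test_that("two segments in one bin superpose (oracle: summing single fields)", {
  # variability disabled so both segments are deterministic
  seg1 <- body_segment(1.0, breathing = list(rate_bpm = 12, depth_var = 0))
  seg2 <- body_segment(1.02, heartbeat = list(rate_bpm = 70, amp_var = 0))
  both <- displacement_field(scene_spec(list(seg1, seg2), 10, 0, seed = 5), dev)
  f1 <- displacement_field(scene_spec(list(seg1), 10, 0, seed = 5), dev)
  f2 <- displacement_field(scene_spec(list(seg2), 10, 0, seed = 5), dev)
  b <- round(1.0 / dev$delta_r) + 1
  expect_equal(both[b, ], f1[b, ] + f2[b, ], tolerance = 1e-12)
})

test_that("segments outside the simulated range are rejected", {
  spec <- scene_spec(list(body_segment(50)), duration = 1, noise_sigma = 0)
  expect_error(displacement_field(spec, dev), "outside the simulated range")
})

test_that("IF cube places a static target at the expected beat frequency", {
  spec <- scene_spec(list(body_segment(1.0)), duration = 0.2, noise_sigma = 0)
  f <- displacement_field(spec, dev)
  cube <- synthesize_if_cube(f, dev, noise_sigma = 0, seed = 1)
  # expected tone: delta_f = mu * 2R/c ~ 400 kHz -> FFT bin 20
  df <- dev$mu * 2 * 1.0 / 299792458
  expect_equal(df, 4e5, tolerance = 0.01)
  m <- range_fft(cube, dev)
  mags <- Mod(m$data[, 1])
  expect_equal(which.max(mags) - 1L, 20L)
  # noiseless, zero displacement: chirps within a frame identical
  expect_equal(cube[1, 1, ], cube[1, 5, ])
})

test_that("a 1 mm displacement step produces the Eq.-6 phase step", {
  expect_equal(4 * pi * 1e-3 / (299792458 / 60e9), 2.513, tolerance = 0.005)
})

test_that("aliasing beat frequencies are rejected", {
  # hand-built field at a range whose beat frequency exceeds the IF Nyquist
  f <- structure(matrix(0, 1, 4), amplitude = 1,
                 amp_mod = matrix(1, 1, 4), time_axis = (0:3) * 0.05,
                 bin_axis = 10)
  expect_error(synthesize_if_cube(f, device_config(), 0, 1), "Nyquist")
})

test_that("fixed seed gives a bit-identical cube and matrix", {
  spec <- scene_spec(list(body_segment(0.5, breathing = list(rate_bpm = 14))),
                     duration = 2, noise_sigma = 0.05, seed = 42)
  f <- displacement_field(spec, dev)
  c1 <- synthesize_if_cube(f, dev, 0.05, seed = 42)
  c2 <- synthesize_if_cube(f, dev, 0.05, seed = 42)
  expect_identical(c1, c2)
  m1 <- synthesize_range_time(f, dev, 0.05, seed = 42)
  m2 <- synthesize_range_time(f, dev, 0.05, seed = 42)
  expect_identical(m1$data, m2$data)
  m3 <- synthesize_range_time(f, dev, 0.05, seed = 43)
  expect_false(identical(m1$data, m3$data))
})

test_that("range-FFT phase round-trips the injected displacement", {
  spec <- scene_spec(list(body_segment(1.0, breathing = list(
    rate_bpm = 15, amplitude_m = 1e-3, depth_var = 0))),
    duration = 10, noise_sigma = 0, seed = 1)
  f <- displacement_field(spec, dev)
  cube <- synthesize_if_cube(f, dev, 0, 1)
  m <- chirp_median(range_fft(cube, dev))
  b <- round(1.0 / dev$delta_r)
  ph <- extract_phase(m, b)
  d <- phase_to_displacement(ph, dev$lambda_c, relative = TRUE)
  truth <- f[b + 1, ] - f[b + 1, 1]
  rel_rmse <- sqrt(mean((d - truth)^2)) / sd(truth)
  expect_lt(rel_rmse, 0.05)
})

test_that("reference streams match the scene", {
  segs <- list(
    body_segment(1.5, breathing = list(rate_bpm = 12, depth_var = 0)),
    body_segment(0.6, heartbeat = list(rate_bpm = 60, amp_var = 0)))
  spec <- scene_spec(segs, duration = 60, noise_sigma = 0, seed = 2)
  refs <- make_reference_streams(spec, dev)
  # 60 BPM, 60 s: ~59-60 QRS complexes ~1.0 s apart
  fs_e <- 1 / diff(refs$ecg$time_s[1:2])
  pk <- which(diff(sign(diff(refs$ecg$value))) < 0) + 1
  pk <- pk[refs$ecg$value[pk] > 0.5 * max(refs$ecg$value)]
  expect_gt(length(pk), 55)
  expect_equal(median(diff(pk)) / fs_e, 1.0, tolerance = 0.02)
  # 12 BPM belt: autocorrelation peak at 5 s
  fs_b <- 1 / diff(refs$belt$time_s[1:2])
  r <- autocorr_rate(refs$belt$value, fs_b, band_bpm = c(10, 22))
  expect_equal(r, 12, tolerance = 0.05)
  # no heartbeat segment: ECG request rejected
  spec2 <- scene_spec(segs[1], duration = 10, noise_sigma = 0)
  expect_error(make_reference_streams(spec2, dev), "no heartbeat segment")
})

test_that("ground-truth labels agree with the scene by construction", {
  sc <- tiny_scene()
  tr <- ground_truth(sc$spec, sc$device)
  expect_equal(tr$breathing_bins, round(1.0 / sc$device$delta_r))
  expect_equal(tr$heartbeat_bins, round(0.6 / sc$device$delta_r))
  expect_equal(tr$breathing_rate(0), 15)
})
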