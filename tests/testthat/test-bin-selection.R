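# helper constructing raw verdicts for the truth-table test
branch_verdict_for_test <- function(decision, strict) {
  structure(list(decision = decision, strict_decision = strict,
                 evidence = list()), class = "branch_verdict")
}

fs <- 20
cr <- selection_criteria()

test_that("clean breathing is detected (combination robust across seeds)", {
  for (s in 1:10) {
    x <- band_filter(sine_window(15, noise = 0.01, seed = s), "breathing",
                     fs = fs)
    vr <- breathing_vr_branch(x, cr)
    sl <- breathing_sublevel_branch(x, cr, fs)
    expect_true(combine_breathing(vr, sl))
  }
})

test_that("the sublevel branch passes on a window without edge partials", {
  # a full-cycle-aligned breathing window over a broadband noise floor has
  # a clean two-cluster diagram; a large half-cycle at the window edge
  # would sit between clusters and (deliberately) spoil the dominance test
  t <- seq(0, 15 - 1 / fs, by = 1 / fs)
  for (s in 1:10) {
    set.seed(s)
    x <- cos(2 * pi * (16 / 60) * t) + 0.05 * sin(2 * pi * 3.7 * t) +
      0.02 * rnorm(length(t))
    sl <- breathing_sublevel_branch(band_filter(x, "breathing", fs = fs),
                                    cr, fs)
    expect_true(sl$decision)
  }
})

test_that("a 40 BPM oscillation fails the breathing count criterion", {
  x <- band_filter(sine_window(40, noise = 0.01), "breathing", fs = fs)
  sl <- breathing_sublevel_branch(x, cr, fs)
  expect_false(sl$decision)
})

test_that("degenerate series are not selected", {
  flat <- rep(1, 300)
  expect_false(breathing_vr_branch(flat, cr)$decision)
  expect_false(breathing_sublevel_branch(flat, cr, fs)$decision)
  expect_false(heartbeat_selection(flat, cr, fs)$decision)
  tiny <- band_filter(rep(0, 300) + 1e-4 * rnorm(300), "breathing", fs = fs)
  expect_false(breathing_sublevel_branch(tiny, cr, fs)$decision ||
                 breathing_vr_branch(tiny, cr)$decision)
})

test_that("white noise is rejected by the breathing pipeline (Monte-Carlo)", {
  fp <- 0
  for (s in 1:40) {
    x <- band_filter(noise_window(seed = s), "breathing", fs = fs)
    vr <- breathing_vr_branch(x, cr)
    sl <- breathing_sublevel_branch(x, cr, fs)
    if (combine_breathing(vr, sl)) fp <- fp + 1
  }
  expect_lte(fp, 2)  # >= 95% rejection
})

test_that("white noise is rejected by the heartbeat pipeline (Monte-Carlo)", {
  fp <- 0
  for (s in 1:40) {
    x <- band_filter(noise_window(seed = s + 100), "heartbeat", fs = fs)
    if (heartbeat_selection(x, cr, fs)$decision) fp <- fp + 1
  }
  expect_lte(fp, 2)
})

test_that("clean pulse trains are selected as heartbeat", {
  hits <- 0
  for (s in 1:20) {
    x <- band_filter(pulse_window(rate_bpm = 55 + 2 * s, seed = s),
                     "heartbeat", fs = fs)
    if (heartbeat_selection(x, cr, fs)$decision) hits <- hits + 1
  }
  expect_gte(hits, 17)
})

test_that("breathing leakage into the heartbeat band is rejected after filtering", {
  # 15 BPM breathing with strong harmonics: the band-pass removes the
  # fundamental; residual harmonics are irregular and fail the criteria
  x <- sine_window(15, amp = 2.5, noise = 0.02, seed = 9)
  xb <- band_filter(x, "heartbeat", fs = fs)
  expect_false(heartbeat_selection(xb, cr, fs)$decision)
})

test_that("combination rule follows the published logic", {
  v <- function(d, s) branch_verdict_for_test(d, s)
  expect_true(combine_breathing(v(TRUE, FALSE), v(TRUE, FALSE)))
  expect_true(combine_breathing(v(TRUE, TRUE), v(FALSE, FALSE)))   # strict solo
  expect_true(combine_breathing(v(FALSE, FALSE), v(TRUE, TRUE)))
  expect_false(combine_breathing(v(FALSE, FALSE), v(FALSE, FALSE)))
  expect_false(combine_breathing(v(TRUE, FALSE), v(FALSE, FALSE)))
})

test_that("strict implies lax for every branch (threshold monotonicity)", {
  for (s in 1:10) {
    x <- band_filter(sine_window(10 + s, noise = 0.05 * s, seed = s),
                     "breathing", fs = fs)
    vr <- breathing_vr_branch(x, cr)
    sl <- breathing_sublevel_branch(x, cr, fs)
    expect_true(!vr$strict_decision || vr$decision)
    expect_true(!sl$strict_decision || sl$decision)
    h <- heartbeat_selection(
      band_filter(pulse_window(60 + 3 * s, seed = s), "heartbeat", fs = fs),
      cr, fs)
    expect_true(!h$strict_decision || h$decision)
  }
})

test_that("heartbeat selection is invariant to positive rescaling", {
  for (s in 1:5) {
    x <- band_filter(pulse_window(70, seed = s), "heartbeat", fs = fs)
    a <- heartbeat_selection(x, cr, fs)$decision
    b <- heartbeat_selection(1000 * x, cr, fs)$decision
    c <- heartbeat_selection(x / 1000, cr, fs)$decision
    expect_equal(a, b)
    expect_equal(a, c)
  }
})

test_that("select_bins recovers labels on a small labeled scene", {
  sc <- tiny_scene(duration = 60, seed = 4)
  sim <- simulate_recording(sc$spec, sc$device, references = FALSE)
  rec <- restrict_bins(sim$recording, 0.4, 1.9)
  mask <- select_bins(rec)
  br_bin <- round(1.0 / sc$device$delta_r)
  hb_bin <- round(0.6 / sc$device$delta_r)
  expect_gte(mean(mask$breathing[mask$bin_index == br_bin, ]), 0.7)
  expect_gte(mean(mask$heartbeat[mask$bin_index == hb_bin, ]), 0.7)
  # specificity: other bins mostly unselected
  other <- !(mask$bin_index %in% c(br_bin, hb_bin))
  expect_lte(mean(mask$breathing[other, ]), 0.1)
  expect_lte(mean(mask$heartbeat[other, ]), 0.1)
  # breathing bin not flagged as heartbeat (masking)
  expect_lte(mean(mask$heartbeat[mask$bin_index == br_bin, ]), 0.3)
})
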