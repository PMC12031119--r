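#' A labeled overnight-style synthetic scene
#'
#' The package's canonical validation world: a sleeper lying feet-first
#' toward the radar. Torso bins (2.0-2.35 m) carry drifting breathing
#' (11-18 BPM, ~1 mm with harmonics and breath-to-breath depth
#' variability); leg bins (0.6-0.75 m) carry heartbeat-only motion
#' (55-80 BPM, 0.05 mm pulse trains of heterogeneous amplitude); every other
#' restricted bin holds weak static clutter so its phase behaves like
#' measurement noise; gross whole-body motion artifacts (broadband 8 mm
#' bursts with amplitude modulation, ~10 s posture shifts) hit every restricted bin at fixed
#' times.
#'
#' @param duration_s scene length in seconds (default 1800 = 30 min).
#' @param seed RNG seed fixing all randomness.
#' @param noise_sigma complex noise std per component.
#' @param n_artifacts number of artifact events, spread evenly; the default
#'   scales with duration (one per 6 minutes, so 5 in the canonical
#'   30-minute scene).
#' @param device a \code{\link{device_config}}.
#' @return a \code{\link{scene_spec}} with attribute \code{truth_bins}
#'   (list of breathing/heartbeat 0-based bins).
#' @export
sleep_scene <- function(duration_s = 1800, seed = 1L, noise_sigma = 0.02,
                        n_artifacts = NULL, device = device_config()) {
  if (is.null(n_artifacts)) n_artifacts <- max(1L, as.integer(round(duration_s / 360)))
  dr <- device$delta_r
  breathing_bins <- 40:47   # 2.00-2.35 m: thorax/abdomen
  heartbeat_bins <- 12:16   # 0.60-0.80 m: legs, heterogeneous signal quality
  restricted <- which((0:(n_range_bins(device) - 1)) * dr >= 0.4 &
                      (0:(n_range_bins(device) - 1)) * dr <= 3.0) - 1L

  br_rate <- drifting_rate(11, 18, period_s = 600)
  hb_rate <- drifting_rate(55, 80, period_s = 400, phase = pi / 3)

  segs <- list()
  amps <- seq(0.6e-3, 1.2e-3, length.out = length(breathing_bins))
  for (i in seq_along(breathing_bins)) {
    segs[[length(segs) + 1L]] <- body_segment(
      range_m = breathing_bins[i] * dr, reflectivity = 1,
      breathing = list(rate_bpm = br_rate, amplitude_m = amps[i]))
  }
  # straddle the method's clarity threshold: the weakest bin is marginal at
  # the default noise floor, the strongest is unambiguous
  hb_amps <- seq(4e-5, 7e-5, length.out = length(heartbeat_bins))
  for (i in seq_along(heartbeat_bins)) {
    segs[[length(segs) + 1L]] <- body_segment(
      range_m = heartbeat_bins[i] * dr, reflectivity = 1,
      heartbeat = list(rate_bpm = hb_rate, amplitude_m = hb_amps[i]))
  }
  for (b in setdiff(restricted, c(breathing_bins, heartbeat_bins))) {
    segs[[length(segs) + 1L]] <- body_segment(range_m = b * dr,
                                              reflectivity = 0.6)
  }

  # gross motion (posture shifts) moves the whole body: bursts span every
  # restricted bin, so artifact windows genuinely lose all selections
  events <- list()
  if (n_artifacts > 0) {
    starts <- duration_s * (seq_len(n_artifacts)) / (n_artifacts + 1)
    for (s in starts) {
      events[[length(events) + 1L]] <-
        artifact_event(start_s = s, duration_s = 10, bins = restricted,
                       amplitude_m = 8e-3)
    }
  }

  spec <- scene_spec(segs, duration = duration_s, noise_sigma = noise_sigma,
                     artifact_events = events, seed = seed)
  attr(spec, "truth_bins") <- list(breathing = breathing_bins,
                                   heartbeat = heartbeat_bins)
  spec
}
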