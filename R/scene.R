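#' A reflecting body segment in a simulated scene
#'
#' A segment sits at a fixed distance from the radar and can carry breathing
#' motion (sinusoid plus optional harmonics, ~1 mm scale), heartbeat motion
#' (Gaussian-windowed pulse train, ~0.05 mm scale), both, or neither (static
#' clutter). Rates may be constants (BPM) or functions of time returning BPM
#' to model slow drift.
#'
#' @param range_m distance from the radar in meters.
#' @param reflectivity amplitude of the reflected tone (arbitrary units).
#' @param breathing \code{NULL} or a list with elements \code{rate_bpm}
#'   (scalar or \code{function(t)}), \code{amplitude_m} (default 1e-3),
#'   \code{harmonics} (fractions of the fundamental for the 2nd/3rd
#'   harmonic, default \code{c(0.2, 0.1)}) and \code{depth_var} (fractional
#'   breath-to-breath depth variability, default 0.2 -- real tidal volumes
#'   are not phase-locked).
#' @param heartbeat \code{NULL} or a list with elements \code{rate_bpm},
#'   \code{amplitude_m} (default 5e-5), \code{pulse_sigma_s} (Gaussian
#'   pulse width, default 0.05 s) and \code{amp_var} (per-beat amplitude
#'   jitter, default 0.05).
#' @return an object of class \code{body_segment}.
#' @export
body_segment <- function(range_m, reflectivity = 1,
                         breathing = NULL, heartbeat = NULL) {
  stopifnot(is.numeric(range_m), range_m >= 0, reflectivity > 0)
  if (!is.null(breathing)) {
    breathing <- utils::modifyList(
      list(rate_bpm = 15, amplitude_m = 1e-3, harmonics = c(0.2, 0.1),
           depth_var = 0.2),
      breathing)
  }
  if (!is.null(heartbeat)) {
    heartbeat <- utils::modifyList(
      list(rate_bpm = 70, amplitude_m = 5e-5, pulse_sigma_s = 0.05,
           amp_var = 0.05),
      heartbeat)
  }
  seg <- list(range_m = range_m, reflectivity = reflectivity,
              breathing = breathing, heartbeat = heartbeat)
  class(seg) <- "body_segment"
  seg
}

#' An artifact event: a large broadband displacement burst
#'
#' Emulates sporadic gross body motion: a smoothed random-walk displacement
#' burst (>= 5 mm scale) across several adjacent bins, accompanied by strong
#' amplitude modulation of the reflected power (gross motion changes the
#' radar cross-section, not only the phase).
#'
#' @param start_s,duration_s event timing in seconds.
#' @param bins integer vector of affected 0-based bin indices.
#' @param amplitude_m peak displacement of the burst (default 8 mm).
#' @return a list of class \code{artifact_event}.
#' @export
artifact_event <- function(start_s, duration_s, bins, amplitude_m = 8e-3) {
  stopifnot(start_s >= 0, duration_s > 0, length(bins) >= 1,
            amplitude_m > 0)
  ev <- list(start_s = start_s, duration_s = duration_s,
             bins = as.integer(bins), amplitude_m = amplitude_m)
  class(ev) <- "artifact_event"
  ev
}

#' A simulated FMCW scene
#'
#' @param segments list of \code{\link{body_segment}} objects.
#' @param duration recording length in seconds.
#' @param noise_sigma per-component standard deviation of the additive
#'   complex Gaussian noise, in the same units as segment reflectivity.
#'   The default 0.02 corresponds to ~8 um displacement noise for a
#'   unit-reflectivity target at 60 GHz, consistent with the micrometer
#'   phase accuracy reported for such sensors.
#' @param artifact_events list of \code{\link{artifact_event}} objects.
#' @param seed integer seed fixing all randomness of the scene.
#' @return an object of class \code{scene_spec}.
#' @export
scene_spec <- function(segments, duration, noise_sigma = 0.02,
                       artifact_events = list(), seed = 1L) {
  stopifnot(is.list(segments), duration > 0, noise_sigma >= 0)
  if (!all(vapply(segments, inherits, TRUE, "body_segment"))) {
    stop("segments must all be body_segment objects")
  }
  if (!all(vapply(artifact_events, inherits, TRUE, "artifact_event"))) {
    stop("artifact_events must all be artifact_event objects")
  }
  spec <- list(segments = segments, duration = duration,
               noise_sigma = noise_sigma,
               artifact_events = artifact_events, seed = as.integer(seed))
  class(spec) <- "scene_spec"
  spec
}

#' Evaluate a rate trajectory (constant or function) on a time grid, in BPM
#' @keywords internal
eval_rate <- function(rate_bpm, t) {
  if (is.function(rate_bpm)) rate_bpm(t) else rep(rate_bpm, length(t))
}

#' A slowly drifting rate trajectory
#'
#' Returns \code{function(t)} oscillating sinusoidally between \code{lo} and
#' \code{hi} BPM with the given drift period, for modeling the slow
#' physiological rate variation seen overnight.
#'
#' @param lo,hi rate bounds in BPM.
#' @param period_s drift period in seconds.
#' @param phase phase offset in radians.
#' @export
drifting_rate <- function(lo, hi, period_s = 300, phase = 0) {
  force(lo); force(hi); force(period_s); force(phase)
  function(t) lo + (hi - lo) * (0.5 + 0.5 * sin(2 * pi * t / period_s + phase))
}

# Instantaneous phase (rad) of an oscillator with rate rate_bpm(t), sampled
# on grid t (uniform step). Integrates 2*pi*f dt by the trapezoid rule.
oscillator_phase <- function(rate_bpm, t) {
  f_hz <- eval_rate(rate_bpm, t) / 60
  dt <- if (length(t) > 1) t[2] - t[1] else 0
  2 * pi * (cumsum(f_hz) - f_hz[1]) * dt
}

# Beat times of an oscillator: upward crossings of 2*pi*k, linearly
# interpolated on a fine internal grid for accuracy at any output rate.
beat_times <- function(rate_bpm, duration, fs_fine = 200) {
  t <- seq(0, duration, by = 1 / fs_fine)
  th <- oscillator_phase(rate_bpm, t)
  k <- seq_len(floor(th[length(th)] / (2 * pi)))
  if (length(k) == 0) return(numeric(0))
  stats::approx(th, t, xout = 2 * pi * k, ties = "ordered")$y
}
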