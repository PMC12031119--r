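# Evaluate expr with a temporarily fixed RNG state (restores on exit).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

n_range_bins <- function(device) device$n_fast_samples %/% 2L

segment_bin <- function(seg, device) as.integer(round(seg$range_m / device$delta_r))

# Smooth unit-variance modulation signal (low-pass filtered white noise with
# ~period_s correlation time), deterministic under seed.
smooth_modulation <- function(n, fs, period_s, seed) {
  with_seed(seed, {
    w <- max(3L, as.integer(round(fs * period_s)))
    z <- stats::filter(stats::rnorm(n + 2 * w), rep(1 / w, w), sides = 2)
    z <- z[w + seq_len(n)]
    z <- z - mean(z)
    s <- stats::sd(z)
    if (is.na(s) || s == 0) rep(0, n) else z / s
  })
}

# Breathing displacement (m) of one segment on time grid t; depth
# variability is a smooth multiplicative envelope so both the radar field
# and the belt reference can reproduce it bit-identically from the seed.
breathing_waveform <- function(br, t, fs, seed) {
  th <- oscillator_phase(br$rate_bpm, t)
  h <- br$harmonics
  d <- sin(th)
  if (length(h) >= 1 && h[1] > 0) d <- d + h[1] * sin(2 * th)
  if (length(h) >= 2 && h[2] > 0) d <- d + h[2] * sin(3 * th)
  if (!is.null(br$depth_var) && br$depth_var > 0) {
    env <- 1 + br$depth_var * smooth_modulation(length(t), fs, 4, seed)
    d <- d * pmax(env, 0.2)
  }
  br$amplitude_m * d
}

# Heartbeat displacement (m): Gaussian pulse train with per-beat amplitude
# jitter, deterministic under seed.
heartbeat_waveform <- function(hb, t, duration, seed) {
  tb <- beat_times(hb$rate_bpm, duration)
  gains <- if (!is.null(hb$amp_var) && hb$amp_var > 0 && length(tb)) {
    with_seed(seed, 1 + hb$amp_var * stats::rnorm(length(tb)))
  } else rep(1, length(tb))
  d <- numeric(length(t))
  sigma <- hb$pulse_sigma_s
  for (k in seq_along(tb)) {
    idx <- which(t >= tb[k] - 4 * sigma & t <= tb[k] + 4 * sigma)
    if (length(idx)) {
      d[idx] <- d[idx] + gains[k] * exp(-(t[idx] - tb[k])^2 / (2 * sigma^2))
    }
  }
  hb$amplitude_m * d
}

#' Per-bin displacement field of a scene
#'
#' Superimposes the breathing, heartbeat and artifact displacements of all
#' segments, assigning each segment to the range bin containing it
#' (\code{round(range_m / delta_r)}, 0-based). Sampled at the frame rate.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param device a \code{\link{device_config}}.
#' @return a numeric matrix [bin x frame] of displacements in meters, with
#'   attributes \code{amplitude} (per-bin reflectivity), \code{amp_mod}
#'   (multiplicative amplitude modulation, [bin x frame], from artifacts),
#'   \code{time_axis} (s) and \code{bin_axis} (m).
#' @export
displacement_field <- function(spec, device = device_config()) {
  stopifnot(inherits(spec, "scene_spec"), inherits(device, "device_config"))
  nb <- n_range_bins(device)
  nf <- floor(spec$duration * device$frame_rate)
  t <- (seq_len(nf) - 1) / device$frame_rate
  field <- matrix(0, nrow = nb, ncol = nf)
  amp <- numeric(nb)
  amp_mod <- matrix(1, nrow = nb, ncol = nf)

  max_r <- (nb - 1) * device$delta_r
  for (i in seq_along(spec$segments)) {
    seg <- spec$segments[[i]]
    if (seg$range_m > max_r) {
      stop(sprintf("segment at %.2f m lies outside the simulated range (max %.2f m)",
                   seg$range_m, max_r))
    }
    b <- segment_bin(seg, device) + 1L
    amp[b] <- amp[b] + seg$reflectivity
    if (!is.null(seg$breathing)) {
      field[b, ] <- field[b, ] +
        breathing_waveform(seg$breathing, t, device$frame_rate,
                           spec$seed + 1000L + i)
    }
    if (!is.null(seg$heartbeat)) {
      field[b, ] <- field[b, ] +
        heartbeat_waveform(seg$heartbeat, t, spec$duration,
                           spec$seed + 2000L + i)
    }
  }

  # artifact bursts: smoothed random walks, deterministic under spec$seed
  if (length(spec$artifact_events) > 0) {
    with_seed(spec$seed + 7919L, {
      for (ev in spec$artifact_events) {
        idx <- which(t >= ev$start_s & t < ev$start_s + ev$duration_s)
        if (length(idx) < 2) next
        w <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / (length(idx) + 1))
        for (b0 in ev$bins) {
          b <- b0 + 1L
          if (b < 1 || b > nb) next
          # broadband burst: slow random-walk component plus white jitter,
          # so gross motion is jerky rather than breathing-like
          rw <- cumsum(stats::rnorm(length(idx)))
          rw <- rw / max(abs(rw))
          jit <- stats::rnorm(length(idx), sd = 0.8)
          burst <- ev$amplitude_m * w * (0.4 * rw + jit)
          field[b, idx] <- field[b, idx] + burst
          amp_mod[b, idx] <- amp_mod[b, idx] +
            2.5 * abs(burst) / ev$amplitude_m
        }
      }
    })
  }

  structure(field, amplitude = amp, amp_mod = amp_mod,
            time_axis = t, bin_axis = (seq_len(nb) - 1) * device$delta_r)
}

#' Synthesize a complex range-time matrix from a displacement field
#'
#' The "matrix" fidelity level: each occupied bin emits
#' \eqn{A(t) \exp(j \phi(t))} with \eqn{\phi(t) = 4\pi (R_b + d(t)) / \lambda}
#' (so displacement maps to phase exactly as the demodulation inverts it),
#' plus i.i.d. complex Gaussian noise. At \code{level = "chirp"} each frame's
#' displacement value is repeated for all chirps of the frame (vital-sign
#' motion is static over the 4.8 ms frame span) with independent noise per
#' chirp.
#'
#' @param field output of \code{\link{displacement_field}}.
#' @param device a \code{\link{device_config}}.
#' @param noise_sigma per-component complex noise std.
#' @param seed RNG seed.
#' @param level \code{"frame"} (default) or \code{"chirp"}.
#' @return a \code{\link{range_time_matrix}}.
#' @export
synthesize_range_time <- function(field, device = device_config(),
                                  noise_sigma = 0.02, seed = 1L,
                                  level = c("frame", "chirp")) {
  level <- match.arg(level)
  nb <- nrow(field); nf <- ncol(field)
  amp <- attr(field, "amplitude")
  amp_mod <- attr(field, "amp_mod")
  bin_axis <- attr(field, "bin_axis")
  lam <- device$lambda_c

  rep_k <- if (level == "chirp") device$chirps_per_frame else 1L
  nt <- nf * rep_k
  data <- matrix(0+0i, nrow = nb, ncol = nt)
  for (b in seq_len(nb)) {
    if (amp[b] > 0) {
      ph <- 4 * pi * (bin_axis[b] + field[b, ]) / lam
      v <- amp[b] * amp_mod[b, ] * exp(1i * ph)
      data[b, ] <- rep(v, each = rep_k)
    }
  }
  if (noise_sigma > 0) {
    with_seed(seed, {
      data <- data + matrix(complex(real = stats::rnorm(nb * nt, sd = noise_sigma),
                                    imaginary = stats::rnorm(nb * nt, sd = noise_sigma)),
                            nrow = nb)
    })
  }
  dt <- if (level == "chirp") device$chirp_interval else device$frame_interval
  time_axis <- if (level == "chirp") {
    frame_start <- rep((seq_len(nf) - 1) * device$frame_interval, each = rep_k)
    frame_start + rep((seq_len(rep_k) - 1) * device$chirp_interval, times = nf)
  } else {
    (seq_len(nf) - 1) * device$frame_interval
  }
  range_time_matrix(data, time_axis, bin_axis, device, level)
}

#' Synthesize a raw IF chirp cube
#'
#' The "cube" fidelity level exercising the range FFT: each occupied bin
#' contributes a complex tone at its beat frequency
#' \eqn{\Delta f = \mu \cdot 2 R / c} with vital-sign phase
#' \eqn{\phi(t) = 4\pi (R + d(t)) / \lambda}, sampled over fast time, plus
#' i.i.d. complex Gaussian noise per sample. Chirps within a frame share the
#' frame's displacement value.
#'
#' @inheritParams synthesize_range_time
#' @return a complex array [frame x chirp x fast-time sample] with the
#'   device attached as attribute \code{device}.
#' @export
synthesize_if_cube <- function(field, device = device_config(),
                               noise_sigma = 0.02, seed = 1L) {
  nb <- nrow(field); nf <- ncol(field)
  amp <- attr(field, "amplitude")
  amp_mod <- attr(field, "amp_mod")
  bin_axis <- attr(field, "bin_axis")
  ns <- device$n_fast_samples
  nc <- device$chirps_per_frame
  ts_fast <- (seq_len(ns) - 1) / device$adc_rate

  occupied <- which(amp > 0)
  for (b in occupied) {
    df <- device$mu * 2 * bin_axis[b] / C_LIGHT
    if (df > device$adc_rate / 2) {
      stop(sprintf("beat frequency %.3g Hz of bin %d exceeds the IF Nyquist %.3g Hz",
                   df, b - 1L, device$adc_rate / 2))
    }
  }

  cube <- array(0+0i, dim = c(nf, nc, ns))
  for (b in occupied) {
    df <- device$mu * 2 * bin_axis[b] / C_LIGHT
    tone <- exp(2i * pi * df * ts_fast)                    # [ns]
    ph <- 4 * pi * (bin_axis[b] + field[b, ]) / device$lambda_c
    gain <- amp[b] * amp_mod[b, ] * exp(1i * ph)           # [nf]
    contrib <- outer(gain, tone)                           # [nf x ns]
    for (ch in seq_len(nc)) cube[, ch, ] <- cube[, ch, ] + contrib
  }
  if (noise_sigma > 0) {
    with_seed(seed, {
      n <- length(cube)
      cube <- cube + array(complex(real = stats::rnorm(n, sd = noise_sigma),
                                   imaginary = stats::rnorm(n, sd = noise_sigma)),
                           dim = dim(cube))
    })
  }
  attr(cube, "device") <- device
  cube
}

#' Reference belt and ECG traces for a scene
#'
#' The belt trace is the summed breathing displacement of all breathing
#' segments plus measurement noise, on the radar frame time base. The ECG is
#' a QRS-like biphasic pulse train (derivative-of-Gaussian) at the heartbeat
#' rate trajectory, sampled at \code{fs_ecg} Hz.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param device a \code{\link{device_config}} (sets the belt time base).
#' @param fs_ecg ECG sampling rate, >= 100 Hz.
#' @return list with data.frames \code{belt} and \code{ecg}
#'   (columns \code{time_s}, \code{value}).
#' @export
make_reference_streams <- function(spec, device = device_config(),
                                   fs_ecg = 100) {
  stopifnot(fs_ecg >= 100)
  has_br <- vapply(spec$segments, function(s) !is.null(s$breathing), TRUE)
  has_hb <- vapply(spec$segments, function(s) !is.null(s$heartbeat), TRUE)
  if (!any(has_br)) stop("scene has no breathing segment; no belt reference")
  if (!any(has_hb)) stop("scene has no heartbeat segment; no ECG reference")

  nf <- floor(spec$duration * device$frame_rate)
  t_belt <- (seq_len(nf) - 1) / device$frame_rate
  belt <- numeric(nf)
  for (i in which(has_br)) {
    belt <- belt + breathing_waveform(spec$segments[[i]]$breathing, t_belt,
                                      device$frame_rate, spec$seed + 1000L + i)
  }
  t_ecg <- seq(0, spec$duration - 1 / fs_ecg, by = 1 / fs_ecg)
  hb <- spec$segments[has_hb][[1]]$heartbeat
  tb <- beat_times(hb$rate_bpm, spec$duration)
  sig <- 0.012  # QRS half-width ~ 25 ms
  ecg <- numeric(length(t_ecg))
  for (tt in tb) {
    idx <- which(t_ecg >= tt - 5 * sig & t_ecg <= tt + 5 * sig)
    if (length(idx)) {
      u <- (t_ecg[idx] - tt) / sig
      ecg[idx] <- ecg[idx] - u * exp(-u^2 / 2)  # biphasic, R peak first
    }
  }
  with_seed(spec$seed + 104729L, {
    belt <- belt + stats::rnorm(length(belt), sd = 0.02 * max(abs(belt), 1e-12))
    ecg <- ecg + stats::rnorm(length(ecg), sd = 0.02)
  })
  list(belt = data.frame(time_s = t_belt, value = belt),
       ecg = data.frame(time_s = t_ecg, value = ecg))
}

#' Ground-truth labels and rate trajectories for a scene
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param device a \code{\link{device_config}}.
#' @return list: \code{breathing_bins}, \code{heartbeat_bins} (0-based bin
#'   indices), and \code{breathing_rate}/\code{heartbeat_rate} functions of
#'   time (BPM; the first matching segment's trajectory).
#' @export
ground_truth <- function(spec, device = device_config()) {
  br_bins <- hb_bins <- integer(0)
  br_rate <- hb_rate <- NULL
  for (seg in spec$segments) {
    b <- segment_bin(seg, device)
    if (!is.null(seg$breathing)) {
      br_bins <- c(br_bins, b)
      if (is.null(br_rate)) br_rate <- seg$breathing$rate_bpm
    }
    if (!is.null(seg$heartbeat)) {
      hb_bins <- c(hb_bins, b)
      if (is.null(hb_rate)) hb_rate <- seg$heartbeat$rate_bpm
    }
  }
  list(breathing_bins = sort(unique(br_bins)),
       heartbeat_bins = sort(unique(hb_bins)),
       breathing_rate = if (!is.null(br_rate)) function(t) eval_rate(br_rate, t),
       heartbeat_rate = if (!is.null(hb_rate)) function(t) eval_rate(hb_rate, t))
}

#' Simulate a full labeled recording
#'
#' Convenience wrapper producing the range-time matrix (or IF cube), the
#' ground truth and the reference streams in one call.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param device a \code{\link{device_config}}.
#' @param fidelity \code{"matrix"} (fast; emit the complex range-time matrix
#'   directly) or \code{"cube"} (emit fast-time samples and run the range
#'   FFT).
#' @param level for matrix fidelity, \code{"frame"} or \code{"chirp"}.
#' @param references logical; also generate belt/ECG traces.
#' @return list with elements \code{recording} (range_time_matrix),
#'   \code{truth}, and optionally \code{belt}, \code{ecg}.
#' @export
simulate_recording <- function(spec, device = device_config(),
                               fidelity = c("matrix", "cube"),
                               level = "frame", references = TRUE) {
  fidelity <- match.arg(fidelity)
  field <- displacement_field(spec, device)
  rec <- if (fidelity == "cube") {
    cube <- synthesize_if_cube(field, device, spec$noise_sigma, spec$seed)
    range_fft(cube, device)
  } else {
    synthesize_range_time(field, device, spec$noise_sigma, spec$seed, level)
  }
  out <- list(recording = rec, truth = ground_truth(spec, device))
  if (references) {
    refs <- tryCatch(make_reference_streams(spec, device),
                     error = function(e) NULL)
    if (!is.null(refs)) { out$belt <- refs$belt; out$ecg <- refs$ecg }
  }
  out
}
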