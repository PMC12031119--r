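#' Breathing/periodicity rate via autocorrelation
#'
#' Finds the non-zero lag with the highest normalized autocorrelation inside
#' the physiologic band's period range and converts it to a rate. The lag is
#' refined by parabolic interpolation around the peak. The rate is undefined
#' (NA) when the best correlation is below \code{min_corr} (no credible
#' periodicity).
#'
#' @param x numeric window (typically 60 s of low-pass filtered phase or a
#'   belt trace).
#' @param fs sampling rate, Hz.
#' @param band_bpm admissible rate band, BPM.
#' @param min_corr definedness floor on the normalized autocorrelation.
#' @return rate in BPM, or \code{NA}.
#' @export
autocorr_rate <- function(x, fs, band_bpm = c(10, 22), min_corr = 0.3) {
  x <- x - mean(x)
  if (stats::sd(x) == 0) return(NA_real_)
  n <- length(x)
  lag_min <- max(1L, as.integer(floor(fs * 60 / band_bpm[2])))
  lag_max <- min(n - 2L, as.integer(ceiling(fs * 60 / band_bpm[1])))
  if (lag_max <= lag_min) return(NA_real_)
  ac <- stats::acf(x, lag.max = lag_max + 1L, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lags <- lag_min:lag_max
  r <- ac[lags + 1L]
  best <- which.max(r)
  if (r[best] < min_corr) return(NA_real_)
  lag <- lags[best]
  # parabolic refinement using the neighbors of the peak
  y0 <- ac[lag]; y1 <- ac[lag + 1L]; y2 <- ac[lag + 2L]
  denom <- y0 - 2 * y1 + y2
  delta <- if (abs(denom) > 1e-12) 0.5 * (y0 - y2) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  60 * fs / (lag + delta)
}

#' Peak score of a window's periodicity (for single-bin baselines)
#' @inheritParams autocorr_rate
#' @return the maximal normalized autocorrelation in the band (0 if
#'   degenerate).
#' @export
autocorr_score <- function(x, fs, band_bpm = c(10, 22)) {
  x <- x - mean(x)
  if (stats::sd(x) == 0) return(0)
  n <- length(x)
  lag_min <- max(1L, as.integer(floor(fs * 60 / band_bpm[2])))
  lag_max <- min(n - 2L, as.integer(ceiling(fs * 60 / band_bpm[1])))
  if (lag_max <= lag_min) return(0)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  max(ac[(lag_min:lag_max) + 1L])
}

# --- stationary wavelet transform (sym4), a-trous scheme ------------------

# sym4 analysis filters (orthonormal; sum of dec_lo = sqrt(2))
SYM4_DEC_LO <- c(0.03222310060404270, -0.012603967262037833,
                 -0.09921954357684722, 0.29785779560527736,
                 0.80373875180591614, 0.49761866763201545,
                 -0.02963552764599851, -0.07576571478927333)
SYM4_DEC_HI <- rev(SYM4_DEC_LO) * (-1)^(seq_along(SYM4_DEC_LO) - 1)

# circular convolution of x with an upsampled filter (holes of 2^(lev-1))
atrous_filter <- function(x, h, lev) {
  n <- length(x)
  gap <- 2^(lev - 1L)
  idx_h <- (seq_along(h) - 1L) * gap
  out <- numeric(n)
  for (k in seq_along(h)) {
    out <- out + h[k] * x[((seq_len(n) - 1L + idx_h[k]) %% n) + 1L]
  }
  out
}

#' Stationary wavelet transform detail coefficients (Symlet-4)
#'
#' Undecimated (a-trous) DWT with circular boundary handling; returns the
#' detail coefficients of levels 1..\code{n_levels}.
#'
#' @param x numeric series.
#' @param n_levels decomposition depth.
#' @return list of numeric vectors, one per level.
#' @export
swt_sym4 <- function(x, n_levels = 3L) {
  approx_c <- x
  details <- vector("list", n_levels)
  for (lev in seq_len(n_levels)) {
    details[[lev]] <- atrous_filter(approx_c, SYM4_DEC_HI, lev)
    approx_c <- atrous_filter(approx_c, SYM4_DEC_LO, lev)
  }
  details
}

# simple local-maxima peak picker with refractory period and threshold
find_peaks <- function(x, min_dist, threshold) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= threshold]
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  }
  sort(kept)
}

# sub-sample peak positions by parabolic interpolation (the sampling grid
# otherwise quantizes inter-beat intervals and hence the rate)
refine_peaks <- function(x, peaks) {
  pos <- as.numeric(peaks)
  inner <- peaks > 1 & peaks < length(x)
  p <- peaks[inner]
  denom <- x[p - 1] - 2 * x[p] + x[p + 1]
  delta <- ifelse(abs(denom) > 1e-12, 0.5 * (x[p - 1] - x[p + 1]) / denom, 0)
  pos[inner] <- p + pmax(pmin(delta, 0.5), -0.5)
  pos
}

#' Heart rate from an ECG window via SWT(Symlet-4) QRS detection
#'
#' Squares and sums the SWT detail coefficients of the levels covering the
#' QRS energy band (~10-25 Hz at the given sampling rate), finds peaks with
#' a 0.3 s refractory period, and returns 60 / median(peak-to-peak
#' interval). Undefined with fewer than 2 peaks.
#'
#' @param ecg numeric ECG window (>= 100 Hz sampling).
#' @param fs sampling rate, Hz.
#' @param refractory_s minimum inter-beat distance, s.
#' @return heart rate in BPM, or \code{NA}.
#' @export
ecg_heart_rate <- function(ecg, fs, refractory_s = 0.3) {
  if (length(ecg) < fs || stats::sd(ecg) == 0) return(NA_real_)
  # level j covers ~ fs/2^(j+1) .. fs/2^j; pick levels overlapping 10-25 Hz
  levs <- which(vapply(1:5, function(j) {
    lo <- fs / 2^(j + 1); hi <- fs / 2^j
    hi > 10 && lo < 25
  }, TRUE))
  if (length(levs) == 0) levs <- 2L
  det <- swt_sym4(ecg, max(levs))
  e <- Reduce(`+`, lapply(levs, function(j) det[[j]]^2))
  # light smoothing over ~40 ms
  w <- max(3L, as.integer(round(0.04 * fs)))
  es <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  es[is.na(es)] <- 0
  thr <- max(0.2 * max(es), 3 * stats::median(es))
  pk <- find_peaks(es, min_dist = as.integer(round(refractory_s * fs)),
                   threshold = thr)
  if (length(pk) < 2) return(NA_real_)
  60 / (stats::median(diff(refine_peaks(es, pk))) / fs)
}

# analytic-signal envelope via FFT (Hilbert transform)
signal_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Heart rate from a radar phase window
#'
#' Amplitude normalization (a documented stand-in for the published
#' amplitude-equalization step: the series is divided by its smoothed
#' analytic-signal envelope, equalizing beat amplitudes), then peak finding
#' with a refractory period; the rate is 60 / median(interval). Undefined if
#' fewer than half the minimum physiological beat count is found.
#'
#' @param x heartbeat-band filtered phase window (60 s typical).
#' @param fs sampling rate, Hz.
#' @param refractory_s minimum inter-beat distance, s.
#' @param min_rate_bpm lowest admissible heart rate (sets the definedness
#'   floor).
#' @param irregularity_max definedness floor on interval regularity:
#'   undefined when IQR(intervals)/median(intervals) exceeds this (noise
#'   produces refractory-limited but irregular peaks; beats are metronomic).
#' @return heart rate in BPM, or \code{NA}.
#' @export
radar_heart_rate <- function(x, fs, refractory_s = 0.3, min_rate_bpm = 40,
                             irregularity_max = 0.25) {
  if (length(x) < fs || stats::sd(x) == 0) return(NA_real_)
  env <- signal_envelope(x - mean(x))
  # envelope smoothed over ~one beat so it tracks beat amplitude without
  # dipping between beats (a short window amplifies inter-beat noise and
  # biases the rate upward through false peaks)
  w <- max(3L, as.integer(round(1.0 * fs)))
  envs <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  envs[is.na(envs)] <- stats::median(env)
  floor_env <- 0.1 * stats::median(envs)
  y <- (x - mean(x)) / pmax(envs, floor_env)
  pk <- find_peaks(y, min_dist = as.integer(round(refractory_s * fs)),
                   threshold = 0.65)
  window_s <- length(x) / fs
  min_beats <- 0.5 * min_rate_bpm * window_s / 60
  if (length(pk) < max(2, min_beats)) return(NA_real_)
  iv <- diff(refine_peaks(y, pk))
  if (stats::IQR(iv) / stats::median(iv) > irregularity_max) return(NA_real_)
  60 / (stats::median(iv) / fs)
}

#' Aggregate per-bin rates into one window rate
#'
#' The median over the bins with a defined rate; \code{NA} if none.
#'
#' @param rates numeric vector of per-bin rates (may contain NA).
#' @return BPM or \code{NA}.
#' @export
aggregate_bins <- function(rates) {
  r <- rates[!is.na(rates)]
  if (length(r) == 0) return(NA_real_)
  stats::median(r)
}

#' Agreement summary between reference and radar rate series
#'
#' Mean absolute error, mean absolute percent error, the share of windows
#' within +/-1 BPM, and Bland-Altman statistics (mean difference
#' reference - radar, with mean +/- 1.96 SD limits of agreement). Windows
#' undefined in either series are excluded; reference zeros are excluded
#' from the MAPE with a message.
#'
#' @param f_ref,f_radar numeric vectors of paired rates (BPM; NA = undefined).
#' @return an object of class \code{error_summary}.
#' @export
error_summary <- function(f_ref, f_radar) {
  stopifnot(length(f_ref) == length(f_radar))
  ok <- !is.na(f_ref) & !is.na(f_radar)
  if (!any(ok)) stop("no windows defined in both series")
  a <- f_ref[ok]; b <- f_radar[ok]
  diffs <- a - b
  mae <- mean(abs(diffs))
  nz <- a != 0
  if (any(!nz)) message(sprintf("excluding %d zero-reference windows from MAPE", sum(!nz)))
  mape <- 100 * mean(abs(diffs[nz]) / a[nz])
  s <- stats::sd(diffs)
  if (is.na(s)) s <- 0
  out <- list(mae = mae, mape = mape,
              pct_within_1bpm = 100 * mean(abs(diffs) <= 1),
              mean_diff = mean(diffs),
              loa_lower = mean(diffs) - 1.96 * s,
              loa_upper = mean(diffs) + 1.96 * s,
              n_windows = sum(ok))
  class(out) <- "error_summary"
  out
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> n = %d windows\n", x$n_windows))
  cat(sprintf("  MAE  = %.3f BPM   MAPE = %.2f%%   within +/-1 BPM: %.1f%%\n",
              x$mae, x$mape, x$pct_within_1bpm))
  cat(sprintf("  Bland-Altman: mean diff %.3f BPM, LoA [%.3f, %.3f]\n",
              x$mean_diff, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Per-window vital rates from selected bins
#'
#' For every merged (60 s) window, computes the rate in every selected bin
#' (autocorrelation in the breathing band; normalized peak finding for
#' heartbeat) and aggregates by the median. Also returns a single-bin
#' baseline: per window, the one bin among \emph{all} restricted bins with
#' the highest in-band autocorrelation score (a standalone single-bin
#' selector that, unlike the median path, gets no help from the
#' topological mask -- mirroring how prior single-bin methods actually
#' operate, including their failure mode of confidently picking a
#' periodic but wrong bin).
#'
#' @param m restricted frame-level \code{\link{range_time_matrix}}.
#' @param merged a \code{merged_mask} from \code{\link{merge_selections}}.
#' @param criteria a \code{\link{selection_criteria}} (bands and filters).
#' @return data.frame with one row per merged window and columns
#'   \code{window_start_s}, \code{breathing_bpm}, \code{heartbeat_bpm},
#'   \code{breathing_bpm_single}, \code{heartbeat_bpm_single},
#'   \code{n_bins_breathing}, \code{n_bins_heartbeat}.
#' @export
compute_rates <- function(m, merged, criteria = selection_criteria()) {
  fs <- 1 / (m$time_axis[2] - m$time_axis[1])
  wlen <- as.integer(round(merged$grid$rate_window_length * fs))
  nw <- nrow(merged$windows)
  nb <- nrow(m$data)
  # per-bin full-length filtered phase, computed once
  lp <- bp <- vector("list", nb)
  for (b in seq_len(nb)) {
    ph <- extract_phase(m, m$bin_index[b])$values
    lp[[b]] <- band_filter(ph, "breathing", fs = fs,
                           lowpass_hz = criteria$breathing_lowpass_hz)
    bp[[b]] <- band_filter(ph, "heartbeat", fs = fs,
                           band_hz = criteria$heartbeat_band_hz)
  }
  out <- data.frame(window_start_s = merged$windows$start_s,
                    breathing_bpm = NA_real_, heartbeat_bpm = NA_real_,
                    breathing_bpm_single = NA_real_,
                    heartbeat_bpm_single = NA_real_,
                    n_bins_breathing = 0L, n_bins_heartbeat = 0L)
  for (w in seq_len(nw)) {
    i0 <- as.integer(round(merged$windows$start_s[w] * fs)) + 1L
    idx <- i0:min(i0 + wlen - 1L, length(lp[[1]]))
    if (length(idx) < wlen) next
    bbins <- which(merged$breathing[, w])
    if (length(bbins)) {
      rates <- vapply(bbins, function(b)
        autocorr_rate(lp[[b]][idx], fs, criteria$breathing_band_bpm),
        numeric(1))
      out$breathing_bpm[w] <- aggregate_bins(rates)
      out$n_bins_breathing[w] <- sum(!is.na(rates))
    }
    hbins <- which(merged$heartbeat[, w])
    if (length(hbins)) {
      rates <- vapply(hbins, function(b)
        radar_heart_rate(bp[[b]][idx], fs), numeric(1))
      out$heartbeat_bpm[w] <- aggregate_bins(rates)
      out$n_bins_heartbeat[w] <- sum(!is.na(rates))
    }
    # standalone single-bin baseline over all restricted bins
    bscore <- vapply(seq_len(nb), function(b)
      autocorr_score(lp[[b]][idx], fs, criteria$breathing_band_bpm),
      numeric(1))
    out$breathing_bpm_single[w] <-
      autocorr_rate(lp[[which.max(bscore)]][idx], fs,
                    criteria$breathing_band_bpm)
    hscore <- vapply(seq_len(nb), function(b)
      autocorr_score(bp[[b]][idx], fs, criteria$heartbeat_band_bpm),
      numeric(1))
    out$heartbeat_bpm_single[w] <-
      radar_heart_rate(bp[[which.max(hscore)]][idx], fs)
  }
  out
}

#' Reference rates on the merged-window grid
#'
#' Belt windows go through the same autocorrelation estimator as the radar;
#' ECG windows through the SWT QRS detector.
#'
#' @param belt,ecg data.frames (\code{time_s}, \code{value}) or NULL.
#' @param windows data.frame with \code{start_s} (merged grid).
#' @param rate_window_s window length, s.
#' @param band_bpm breathing band for the belt estimator.
#' @return data.frame with \code{window_start_s}, \code{belt_bpm},
#'   \code{ecg_bpm}.
#' @export
reference_rates <- function(belt = NULL, ecg = NULL, windows,
                            rate_window_s = 60, band_bpm = c(10, 22)) {
  out <- data.frame(window_start_s = windows$start_s,
                    belt_bpm = NA_real_, ecg_bpm = NA_real_)
  for (w in seq_len(nrow(windows))) {
    t0 <- windows$start_s[w]; t1 <- t0 + rate_window_s
    if (!is.null(belt)) {
      fs_b <- 1 / (belt$time_s[2] - belt$time_s[1])
      seg <- belt$value[belt$time_s >= t0 & belt$time_s < t1]
      if (length(seg) >= rate_window_s * fs_b - 1) {
        out$belt_bpm[w] <- autocorr_rate(seg, fs_b, band_bpm)
      }
    }
    if (!is.null(ecg)) {
      fs_e <- 1 / (ecg$time_s[2] - ecg$time_s[1])
      seg <- ecg$value[ecg$time_s >= t0 & ecg$time_s < t1]
      if (length(seg) >= rate_window_s * fs_e - 1) {
        out$ecg_bpm[w] <- ecg_heart_rate(seg, fs_e)
      }
    }
  }
  out
}
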