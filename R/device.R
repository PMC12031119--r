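#' Speed of light in vacuum (m/s)
#' @keywords internal
C_LIGHT <- 299792458

#' FMCW device configuration
#'
#' Holds the chirp/frame timing and RF parameters of an FMCW radar and the
#' quantities derived from them: the chirp slope \code{mu = B/T}, the
#' wavelength \code{lambda_c = c/fc} and the range resolution
#' \code{delta_r = c/(2B)}. Defaults mirror a 60 GHz sensor configured with a
#' 3 GHz sweep, 12 chirps per 50 ms frame and 401 us between chirp starts,
#' i.e. a 5 cm range resolution and a 20 Hz frame rate.
#'
#' @param fc carrier frequency in Hz.
#' @param B sweep bandwidth in Hz.
#' @param T_sweep chirp sweep duration in seconds.
#' @param chirp_interval time between starts of consecutive chirps (s).
#' @param chirps_per_frame number of chirps in one frame.
#' @param frame_interval time between frame starts (s).
#' @param n_fast_samples ADC samples per chirp (fast time).
#' @return an object of class \code{device_config}.
#' @examples
#' dev <- device_config()
#' dev$delta_r   # 0.05 m
#' @export
device_config <- function(fc = 60e9, B = 3e9, T_sweep = 50e-6,
                          chirp_interval = 401e-6, chirps_per_frame = 12L,
                          frame_interval = 0.05, n_fast_samples = 200L) {
  stopifnot(fc > 0, B > 0, T_sweep > 0, chirp_interval > 0,
            frame_interval > 0, chirps_per_frame >= 1, n_fast_samples >= 2)
  if (chirps_per_frame * chirp_interval > frame_interval) {
    stop("chirps_per_frame * chirp_interval must fit inside frame_interval")
  }
  dev <- list(
    fc = fc, B = B, T_sweep = T_sweep,
    mu = B / T_sweep,
    chirp_interval = chirp_interval,
    chirps_per_frame = as.integer(chirps_per_frame),
    frame_interval = frame_interval,
    n_fast_samples = as.integer(n_fast_samples),
    lambda_c = C_LIGHT / fc,
    delta_r = range_resolution(B),
    frame_rate = 1 / frame_interval,
    # fast-time sampling rate chosen so that one sweep yields n_fast_samples
    adc_rate = n_fast_samples / T_sweep
  )
  class(dev) <- "device_config"
  dev
}

#' @export
print.device_config <- function(x, ...) {
  cat("<device_config>\n")
  cat(sprintf("  fc = %.3g GHz, B = %.3g GHz, mu = %.3g Hz/s\n",
              x$fc / 1e9, x$B / 1e9, x$mu))
  cat(sprintf("  delta_r = %.3g m, lambda = %.3g mm\n",
              x$delta_r, x$lambda_c * 1e3))
  cat(sprintf("  %d chirps / %.0f ms frame (frame rate %.1f Hz), %d fast samples\n",
              x$chirps_per_frame, x$frame_interval * 1e3, x$frame_rate,
              x$n_fast_samples))
  invisible(x)
}

#' Range resolution of an FMCW sweep
#'
#' \deqn{\Delta R = c / (2B)}
#'
#' @param B sweep bandwidth in Hz; must be positive.
#' @return range resolution in meters.
#' @examples
#' range_resolution(3e9)  # 0.05 m
#' @export
range_resolution <- function(B) {
  if (!is.numeric(B) || length(B) != 1 || !is.finite(B) || B <= 0) {
    stop("bandwidth B must be a single positive number")
  }
  C_LIGHT / (2 * B)
}

#' Time spanned by the chirps of one frame (s)
#' @param device a \code{device_config}.
#' @return frame span in seconds (start of first chirp to end of last).
#' @export
frame_span <- function(device) {
  stopifnot(inherits(device, "device_config"))
  device$chirps_per_frame * device$chirp_interval
}
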