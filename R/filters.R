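# --- Butterworth design (bilinear transform) ------------------------------

poly_from_roots <- function(r) {
  p <- 1+0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

# digital Butterworth coefficients (b, a), lowpass or highpass
butter_coef <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) stop("cutoff must lie in (0, fs/2)")
  wc <- 2 * fs * tan(pi * fc / fs)            # pre-warped analog cutoff
  k <- seq_len(n)
  p_norm <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # left-half-plane
  p <- if (type == "low") wc * p_norm else wc / p_norm
  pd <- (2 * fs + p) / (2 * fs - p)           # bilinear map of poles
  zd <- rep(if (type == "low") -1 + 0i else 1 + 0i, n)
  a <- Re(poly_from_roots(pd))
  b <- Re(poly_from_roots(zd))
  a <- a / a[1]
  z0 <- if (type == "low") 1 else -1          # unit gain at DC / Nyquist
  zp <- z0^(0:n)
  g <- sum(b * zp) / sum(a * zp)
  list(b_norm = b / g, a = a)
}

apply_ba <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[-seq_len(nb - 1)]
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

# forward-backward (zero-phase) filtering with odd-reflection padding
filtfilt_ba <- function(coef, x, padlen) {
  n <- length(x)
  padlen <- max(0L, min(as.integer(padlen), n - 1L))
  if (padlen > 0) {
    pre <- 2 * x[1] - x[(padlen + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - padlen)]
    xx <- c(pre, x, post)
  } else xx <- x
  y <- apply_ba(coef$b_norm, coef$a, xx)
  y <- rev(apply_ba(coef$b_norm, coef$a, rev(y)))
  if (padlen > 0) y[padlen + seq_len(n)] else y
}

#' Zero-phase band filtering for vital-sign series
#'
#' Forward-backward (zero-phase) 4th-order Butterworth filtering. Kinds:
#' \describe{
#'   \item{breathing}{5 Hz low-pass (keeps the detailed breathing waveform,
#'     rejects high-frequency noise).}
#'   \item{heartbeat}{0.65-5 Hz band-pass, realized as a high-pass/low-pass
#'     cascade (removes breathing and high-frequency noise, keeps heartbeat
#'     waveforms).}
#' }
#' Edge transients are controlled with odd-reflection padding scaled to the
#' lowest cutoff.
#'
#' @param x numeric series or \code{phase_series}.
#' @param kind \code{"breathing"} or \code{"heartbeat"}.
#' @param fs sampling rate in Hz (taken from a \code{phase_series} input).
#' @param lowpass_hz,band_hz cutoff overrides.
#' @param order Butterworth order (per pass).
#' @return filtered numeric series of the same length.
#' @export
band_filter <- function(x, kind = c("breathing", "heartbeat"), fs = 20,
                        lowpass_hz = 5.0, band_hz = c(0.65, 5.0),
                        order = 4L) {
  kind <- match.arg(kind)
  if (inherits(x, "phase_series")) { fs <- x$fs; x <- x$values }
  hi <- if (kind == "breathing") lowpass_hz else band_hz[2]
  if (hi >= fs / 2) stop("upper cutoff must be below the Nyquist frequency")
  n <- length(x)
  if (n < 4) return(x)
  if (kind == "breathing") {
    lp <- butter_coef(order, lowpass_hz, fs, "low")
    filtfilt_ba(lp, x, padlen = ceiling(3 * fs / lowpass_hz))
  } else {
    lo <- band_hz[1]
    hp <- butter_coef(order, lo, fs, "high")
    lp <- butter_coef(order, band_hz[2], fs, "low")
    y <- filtfilt_ba(hp, x - mean(x), padlen = ceiling(3 * fs / lo))
    filtfilt_ba(lp, y, padlen = ceiling(3 * fs / band_hz[2]))
  }
}
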