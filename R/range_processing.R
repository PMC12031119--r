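#' Complex range-time matrix
#'
#' Rows are range bins, columns are chirps (level \code{"chirp"}) or frames
#' (level \code{"frame"}) across time.
#'
#' @param data complex matrix [bin x time].
#' @param time_axis time of each column in seconds (uniform).
#' @param bin_axis range of each bin center in meters (strictly increasing).
#' @param device the \code{\link{device_config}} that produced the data.
#' @param level \code{"chirp"} or \code{"frame"}.
#' @param bin_index 0-based original bin indices (kept through
#'   \code{\link{restrict_bins}}).
#' @return an object of class \code{range_time_matrix}.
#' @export
range_time_matrix <- function(data, time_axis, bin_axis, device,
                              level = c("frame", "chirp"),
                              bin_index = seq_len(nrow(data)) - 1L) {
  level <- match.arg(level)
  stopifnot(is.matrix(data), is.complex(data),
            length(time_axis) == ncol(data),
            length(bin_axis) == nrow(data),
            length(bin_index) == nrow(data))
  if (nrow(data) > 1 && any(diff(bin_axis) <= 0)) {
    stop("bin_axis must be strictly increasing")
  }
  m <- list(data = data, time_axis = time_axis, bin_axis = bin_axis,
            device = device, level = level, bin_index = as.integer(bin_index))
  class(m) <- "range_time_matrix"
  m
}

#' @export
print.range_time_matrix <- function(x, ...) {
  cat(sprintf("<range_time_matrix> %d bins x %d %s samples, %.2f-%.2f m\n",
              nrow(x$data), ncol(x$data), x$level,
              min(x$bin_axis), max(x$bin_axis)))
  invisible(x)
}

hanning_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Range FFT of an IF chirp cube
#'
#' Applies a Hanning window along fast time (to limit spectral leakage) and
#' an FFT per chirp, then stacks the positive-frequency half of each
#' spectrum into a chirp-level range-time matrix. The spectrum is divided by
#' the window's coherent gain \code{sum(w)} so that a unit-amplitude tone at
#' a bin center appears with magnitude ~1.
#'
#' @param cube complex array [frame x chirp x fast-time] from
#'   \code{\link{synthesize_if_cube}} (or equivalent layout).
#' @param device a \code{\link{device_config}}.
#' @return a \code{\link{range_time_matrix}} at chirp level.
#' @export
range_fft <- function(cube, device = attr(cube, "device")) {
  stopifnot(is.array(cube), length(dim(cube)) == 3)
  if (any(!is.finite(Re(cube))) || any(!is.finite(Im(cube)))) {
    stop("cube contains non-finite samples")
  }
  ns <- dim(cube)[3]
  if (ns < 2) stop("fast-time length must be >= 2")
  nf <- dim(cube)[1]; nc <- dim(cube)[2]
  w <- hanning_window(ns)
  cg <- sum(w)
  nb <- ns %/% 2L
  flat <- matrix(aperm(cube, c(3, 2, 1)), nrow = ns)  # [ns x (nc*nf)]
  flat <- flat * w
  spec <- stats::mvfft(flat) / cg
  data <- spec[seq_len(nb), , drop = FALSE]            # bins x chirps
  frame_start <- rep((seq_len(nf) - 1) * device$frame_interval, each = nc)
  time_axis <- frame_start + rep((seq_len(nc) - 1) * device$chirp_interval,
                                 times = nf)
  range_time_matrix(data, time_axis, (seq_len(nb) - 1) * device$delta_r,
                    device, level = "chirp")
}

# wrap angles into (-pi, pi]
wrap_to_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# cumulative phase unwrapping with threshold pi
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  adj <- cumsum(-round(d / (2 * pi)) * 2 * pi)
  c(p[1], p[-1] + adj)
}

#' Reduce a chirp-level matrix to frame level
#'
#' Summarizes the \code{chirps_per_frame} chirps of each frame into one
#' value per bin. With \code{method = "median"} the median is taken
#' separately over the per-chirp magnitudes and the per-chirp phases; phases
#' are first re-wrapped into a common branch around their circular mean so a
#' frame straddling the +/-pi cut does not corrupt the median. With
#' \code{method = "first"} the first chirp of each frame is used (the
#' baseline mode for with/without comparisons). An incomplete final frame is
#' dropped with a message.
#'
#' @param m a chirp-level \code{\link{range_time_matrix}}.
#' @param method \code{"median"} or \code{"first"}.
#' @return a frame-level \code{\link{range_time_matrix}}; timestamps are the
#'   frame starts.
#' @export
chirp_median <- function(m, method = c("median", "first")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "range_time_matrix"))
  if (m$level != "chirp") {
    if (m$device$chirps_per_frame == 1L) return(m)  # idempotent degenerate case
    stop("chirp_median expects a chirp-level matrix")
  }
  nc <- m$device$chirps_per_frame
  nt <- ncol(m$data)
  nframes <- nt %/% nc
  if (nframes * nc < nt) {
    message(sprintf("dropping incomplete final frame (%d leftover chirps)",
                    nt - nframes * nc))
  }
  nb <- nrow(m$data)
  out <- matrix(0+0i, nrow = nb, ncol = nframes)
  for (f in seq_len(nframes)) {
    block <- m$data[, ((f - 1) * nc + 1):(f * nc), drop = FALSE]
    if (method == "first") {
      out[, f] <- block[, 1]
    } else {
      mag <- apply(Mod(block), 1, stats::median)
      ph <- vapply(seq_len(nb), function(b) {
        p <- Arg(block[b, ])
        ctr <- Arg(sum(exp(1i * p)))
        ctr + stats::median(wrap_to_pi(p - ctr))
      }, numeric(1))
      out[, f] <- complex(modulus = mag, argument = ph)
    }
  }
  time_axis <- m$time_axis[seq(1, by = nc, length.out = nframes)]
  range_time_matrix(out, time_axis, m$bin_axis, m$device,
                    level = "frame", bin_index = m$bin_index)
}

#' Extract the unwrapped phase series of one range bin
#'
#' Arctangent demodulation \code{atan2(Im, Re)} followed by unwrapping with
#' threshold pi, per bin independently.
#'
#' @param m a \code{\link{range_time_matrix}}.
#' @param bin 0-based original bin index.
#' @return object of class \code{phase_series}: list with \code{values}
#'   (rad), \code{fs} (Hz), \code{bin}.
#' @export
extract_phase <- function(m, bin) {
  row <- match(as.integer(bin), m$bin_index)
  if (is.na(row)) stop(sprintf("bin %d is not present in the matrix", bin))
  p <- unwrap_phase(Arg(m$data[row, ]))
  fs <- 1 / (m$time_axis[2] - m$time_axis[1])
  structure(list(values = p, fs = fs, bin = as.integer(bin)),
            class = "phase_series")
}

#' Extract the magnitude series of one range bin
#' @inheritParams extract_phase
#' @return object of class \code{magnitude_series}.
#' @export
extract_magnitude <- function(m, bin) {
  row <- match(as.integer(bin), m$bin_index)
  if (is.na(row)) stop(sprintf("bin %d is not present in the matrix", bin))
  fs <- 1 / (m$time_axis[2] - m$time_axis[1])
  structure(list(values = Mod(m$data[row, ]), fs = fs, bin = as.integer(bin)),
            class = "magnitude_series")
}

#' Convert phase to displacement
#'
#' Inverts the phase-displacement relation \eqn{\phi = 4\pi d / \lambda}:
#' \code{d = phi * lambda / (4 pi)}, in meters. With
#' \code{relative = TRUE} the series is referenced to its first sample
#' (displacement relative to the window start).
#'
#' @param phase numeric vector of unwrapped phase (rad) or a
#'   \code{phase_series}.
#' @param lambda wavelength in meters; must be positive.
#' @param relative reference the output to the first sample.
#' @return displacement in meters.
#' @export
phase_to_displacement <- function(phase, lambda, relative = FALSE) {
  if (inherits(phase, "phase_series")) phase <- phase$values
  stopifnot(lambda > 0)
  d <- phase * lambda / (4 * pi)
  if (relative && length(d)) d <- d - d[1]
  d
}

#' Restrict a range-time matrix to bins of interest
#'
#' Keeps bins whose centers lie in \code{[min_m, max_m]} (default 0.4-3 m:
#' closer bins are corrupted by TX/RX crosstalk; farther ones are dominated
#' by multipath). Original bin indices are preserved in the metadata.
#'
#' @param m a \code{\link{range_time_matrix}}.
#' @param min_m,max_m range limits in meters.
#' @return the restricted \code{\link{range_time_matrix}}.
#' @export
restrict_bins <- function(m, min_m = 0.4, max_m = 3.0) {
  stopifnot(inherits(m, "range_time_matrix"))
  if (max_m < min_m) stop("max_m must be >= min_m")
  keep <- which(m$bin_axis >= min_m & m$bin_axis <= max_m)
  if (length(keep) == 0) stop("no bins remain after restriction")
  range_time_matrix(m$data[keep, , drop = FALSE], m$time_axis,
                    m$bin_axis[keep], m$device, m$level,
                    bin_index = m$bin_index[keep])
}
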