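#' 90th percentile of per-bin magnitude standard deviations in a window
#'
#' The magnitude std over a window discriminates static from moving
#' scatterers; taking the 90th percentile across the restricted bins
#' summarizes the most variable bins while ignoring a single extreme one.
#' Percentiles use linear interpolation between order statistics
#' (\code{quantile} type 7).
#'
#' @param mag_window numeric matrix [bin x sample] of magnitudes.
#' @return scalar.
#' @export
window_std_p90 <- function(mag_window) {
  sds <- apply(mag_window, 1, stats::sd)
  unname(stats::quantile(sds, 0.9, type = 7))
}

# sample skewness g1 and excess kurtosis g2 (moment estimators)
moment_shape <- function(x) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) return(c(NA_real_, NA_real_))
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  c(m3 / m2^1.5, m4 / m2^2 - 3)
}

#' Mean per-bin skewness and excess kurtosis of a magnitude window
#'
#' Artifact-free magnitude windows are approximately Gaussian (skewness ~ 0,
#' excess kurtosis ~ 0); gross motion shifts and heavy-tails the
#' distribution. Zero-variance bins are excluded. The excess-kurtosis
#' convention (normal = 0) makes the |kurtosis| > 3 exceedance threshold a
#' genuine heavy-tail flag; set \code{excess = FALSE} for the Pearson
#' convention.
#'
#' @param mag_window numeric matrix [bin x sample], >= 4 samples per bin.
#' @param excess use excess kurtosis (default) or Pearson kurtosis.
#' @return named vector: \code{mean_skewness}, \code{mean_kurtosis}.
#' @export
window_shape_stats <- function(mag_window, excess = TRUE) {
  stopifnot(ncol(mag_window) >= 4)
  st <- t(apply(mag_window, 1, moment_shape))
  ok <- stats::complete.cases(st)
  k <- st[ok, 2]
  if (!excess) k <- k + 3
  c(mean_skewness = mean(st[ok, 1]), mean_kurtosis = mean(k))
}

#' Per-window artifact metrics for a recording
#'
#' @param m restricted frame-level \code{\link{range_time_matrix}}.
#' @param windows data.frame with \code{start_s}.
#' @param window_s window length in seconds.
#' @return data.frame with \code{window_start_s}, \code{std_p90},
#'   \code{mean_skewness}, \code{mean_kurtosis}.
#' @export
artifact_metrics <- function(m, windows, window_s = 15) {
  fs <- 1 / (m$time_axis[2] - m$time_axis[1])
  wlen <- as.integer(round(window_s * fs))
  mags <- Mod(m$data)
  nw <- nrow(windows)
  out <- data.frame(window_start_s = windows$start_s,
                    std_p90 = NA_real_, mean_skewness = NA_real_,
                    mean_kurtosis = NA_real_)
  for (w in seq_len(nw)) {
    i0 <- as.integer(round(windows$start_s[w] * fs)) + 1L
    blk <- mags[, i0:(i0 + wlen - 1L), drop = FALSE]
    out$std_p90[w] <- window_std_p90(blk)
    sh <- window_shape_stats(blk)
    out$mean_skewness[w] <- sh[1]
    out$mean_kurtosis[w] <- sh[2]
  }
  out
}

#' Group-level artifact statistics by selection status
#'
#' Splits windows into "no bin selected" and "at least one bin selected"
#' groups and reports per group: the quartiles of the std_p90 values, and
#' the percentage of windows with |skewness| > 1 and |kurtosis| > 3.
#'
#' @param metrics output of \code{\link{artifact_metrics}}.
#' @param selected logical vector, one entry per window: any bin selected.
#' @param skew_thresh,kurt_thresh exceedance thresholds.
#' @return data.frame with one row per group (\code{selected},
#'   \code{none_selected}); empty groups yield NA rows.
#' @export
group_exceedance <- function(metrics, selected, skew_thresh = 1,
                             kurt_thresh = 3) {
  stopifnot(nrow(metrics) == length(selected))
  one <- function(sub) {
    if (nrow(sub) == 0) {
      return(data.frame(n = 0L, std_q25 = NA_real_, std_q50 = NA_real_,
                        std_q75 = NA_real_, pct_skew_gt = NA_real_,
                        pct_kurt_gt = NA_real_))
    }
    q <- stats::quantile(sub$std_p90, c(0.25, 0.5, 0.75), type = 7)
    data.frame(n = nrow(sub), std_q25 = q[[1]], std_q50 = q[[2]],
               std_q75 = q[[3]],
               pct_skew_gt = 100 * mean(abs(sub$mean_skewness) > skew_thresh),
               pct_kurt_gt = 100 * mean(abs(sub$mean_kurtosis) > kurt_thresh))
  }
  out <- rbind(one(metrics[selected, , drop = FALSE]),
               one(metrics[!selected, , drop = FALSE]))
  out$group <- c("selected", "none_selected")
  out[, c("group", setdiff(names(out), "group"))]
}
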