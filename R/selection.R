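#' Criteria and thresholds for range-bin selection
#'
#' All empirical thresholds of the selection algorithm live here so a
#' sensitivity analysis is a loop over configurations. Defaults follow the
#' published parameter values where stated (bands, minSamp, embedding) and
#' documented package defaults elsewhere (proximity/dominance factors, the
#' strict-criteria multiplier, the heartbeat eps fraction).
#'
#' @param breathing_band_bpm physiological breathing range, BPM.
#' @param heartbeat_band_bpm physiological heart-rate range, BPM.
#' @param breathing_lowpass_hz low-pass cutoff for the breathing branches.
#' @param heartbeat_band_hz band-pass range for the heartbeat branch.
#' @param dbscan_min_samples_vr minSamp for the Vietoris-Rips H1 diagram
#'   (lone-outlier search).
#' @param birth_proximity_tol tolerated relative distance between an H1
#'   outlier's birth and the maximal finite H0 death.
#' @param lifespan_dominance_factor required multiple between a signal
#'   lifespan and the competing noise lifespan.
#' @param strict_factor uniform multiplier tightening every threshold for
#'   the single-branch ("strict") acceptance path.
#' @param heartbeat_eps_fraction DBSCAN eps for the heartbeat branch, as a
#'   fraction of the window's amplitude range (the data-driven spread did
#'   not work well there).
#' @param signal_amp_fraction minimal signal-cluster lifespan as a fraction
#'   of the window amplitude range (sublevel branches).
#' @param tau,m time-delay embedding parameters (samples / dimension).
#' @param vr_max_points farthest-point subsampling budget for the
#'   Vietoris-Rips branch point cloud.
#' @param spread_method reading of the diagram-spread scale: single-linkage
#'   \code{"connection"} scale (default) or plain \code{"diameter"}.
#' @param minsamp_mode \code{"per_window"} scales the sublevel minSamp rates
#'   (10 and 40 BPM) to expected counts in the window; \code{"literal"}
#'   uses the rates as raw counts.
#' @return an object of class \code{selection_criteria}.
#' @export
selection_criteria <- function(breathing_band_bpm = c(10, 22),
                               heartbeat_band_bpm = c(40, 200),
                               breathing_lowpass_hz = 5.0,
                               heartbeat_band_hz = c(0.65, 5.0),
                               dbscan_min_samples_vr = 2L,
                               birth_proximity_tol = 0.2,
                               lifespan_dominance_factor = 2.0,
                               strict_factor = 1.5,
                               heartbeat_eps_fraction = 0.15,
                               signal_amp_fraction = 0.6,
                               tau = 10L, m = 3L,
                               vr_max_points = 80L,
                               spread_method = "connection",
                               minsamp_mode = c("per_window", "literal")) {
  minsamp_mode <- match.arg(minsamp_mode)
  stopifnot(birth_proximity_tol > 0, lifespan_dominance_factor > 0,
            strict_factor > 0, heartbeat_eps_fraction > 0,
            signal_amp_fraction > 0,
            breathing_band_bpm[1] < breathing_band_bpm[2],
            heartbeat_band_bpm[1] < heartbeat_band_bpm[2],
            heartbeat_band_hz[1] < heartbeat_band_hz[2])
  cr <- list(breathing_band_bpm = breathing_band_bpm,
             heartbeat_band_bpm = heartbeat_band_bpm,
             breathing_lowpass_hz = breathing_lowpass_hz,
             heartbeat_band_hz = heartbeat_band_hz,
             dbscan_min_samples_vr = as.integer(dbscan_min_samples_vr),
             birth_proximity_tol = birth_proximity_tol,
             lifespan_dominance_factor = lifespan_dominance_factor,
             strict_factor = strict_factor,
             heartbeat_eps_fraction = heartbeat_eps_fraction,
             signal_amp_fraction = signal_amp_fraction,
             tau = as.integer(tau), m = as.integer(m),
             vr_max_points = as.integer(vr_max_points),
             spread_method = spread_method,
             minsamp_mode = minsamp_mode)
  class(cr) <- "selection_criteria"
  cr
}

branch_verdict <- function(decision, strict_decision, evidence = list()) {
  structure(list(decision = isTRUE(decision),
                 strict_decision = isTRUE(strict_decision),
                 evidence = evidence),
            class = "branch_verdict")
}

# Expected event count bounds for a rate band (BPM) in a window of length
# W s. The lower bound rounds up: a signal at the band minimum produces at
# least ceil(rate*W/60) complete oscillations-per-window-or-more, and
# admitting floor() would accept slower-than-band phenomena (two gross
# motion excursions in 15 s masquerade as 8 BPM "breathing").
count_bounds <- function(band_bpm, window_s) {
  c(ceiling(band_bpm[1] * window_s / 60), ceiling(band_bpm[2] * window_s / 60))
}

#' Vietoris-Rips branch of the breathing decision
#'
#' Embeds the (already low-pass filtered) 15 s phase window with the
#' time-delay embedding, computes Rips H0/H1 persistence in birth-lifespan
#' form, and asks DBSCAN for lone H1 outliers against the H1 noise cluster.
#' An outlier counts as breathing evidence if its birth is close to the
#' maximal finite H0 death (the loop forms when all points connect) or falls
#' inside the noise cluster's birth range, and its lifespan dominates both
#' the noise cluster's and the maximal finite H0 lifespan. The strict
#' verdict re-tests with every threshold tightened by the strict factor.
#'
#' @param x low-pass filtered phase window (numeric).
#' @param criteria a \code{\link{selection_criteria}}.
#' @return a \code{branch_verdict}.
#' @export
breathing_vr_branch <- function(x, criteria = selection_criteria()) {
  cr <- criteria
  if (length(x) <= (cr$m - 1L) * cr$tau + 2L || stats::sd(x) == 0) {
    return(branch_verdict(FALSE, FALSE, list(reason = "degenerate series")))
  }
  cloud <- time_delay_embed(x, cr$tau, cr$m)
  cloud <- subsample_cloud(cloud, cr$vr_max_points)
  per <- rips_persistence(cloud, maxdim = 1L)
  h0d <- per$h0$pairs[!per$h0$essential, 2]
  if (length(h0d) == 0) {
    return(branch_verdict(FALSE, FALSE, list(reason = "no finite H0 deaths")))
  }
  max_h0_death <- max(h0d)   # births are 0, so death == lifespan for Rips H0
  h1 <- to_birth_lifespan(per$h1)$pairs
  if (nrow(h1) == 0) {
    return(branch_verdict(FALSE, FALSE, list(reason = "no H1 features")))
  }

  if (nrow(h1) == 1) {
    # single H1 point: treat as outlier without a noise cluster
    outliers <- h1
    noise <- h1[0, , drop = FALSE]
  } else {
    eps <- diagram_spread(h1, method = cr$spread_method)
    labels <- dbscan_diagram(h1, eps, cr$dbscan_min_samples_vr)
    outliers <- h1[labels == 0L, , drop = FALSE]
    if (any(labels > 0L)) {
      main <- as.integer(names(which.max(table(labels[labels > 0L]))))
      noise <- h1[labels == main, , drop = FALSE]
    } else {
      noise <- h1[0, , drop = FALSE]
    }
  }
  if (nrow(outliers) == 0) {
    return(branch_verdict(FALSE, FALSE, list(reason = "no H1 outliers")))
  }

  noise_max_life <- if (nrow(noise)) max(noise[, 2]) else 0
  noise_birth_rng <- if (nrow(noise)) range(noise[, 1]) else c(NA_real_, NA_real_)

  test <- function(tol, factor) {
    birth_ok <- abs(outliers[, 1] - max_h0_death) <= tol * max_h0_death
    if (nrow(noise)) {
      birth_ok <- birth_ok | (outliers[, 1] >= noise_birth_rng[1] &
                              outliers[, 1] <= noise_birth_rng[2])
    }
    life_ok <- outliers[, 2] >= factor * max(noise_max_life, max_h0_death)
    any(birth_ok & life_ok)
  }
  dec <- test(cr$birth_proximity_tol, cr$lifespan_dominance_factor)
  strict <- test(cr$birth_proximity_tol / cr$strict_factor,
                 cr$lifespan_dominance_factor * cr$strict_factor)
  branch_verdict(dec, strict && dec,
                 list(max_h0_death = max_h0_death,
                      n_outliers = nrow(outliers),
                      noise_max_life = noise_max_life,
                      max_outlier_life = max(outliers[, 2])))
}

# shared sublevel-cluster machinery for the two sublevel-set branches
sublevel_cluster_verdict <- function(x, eps, min_samples, count_band,
                                     dominance, amp_fraction, strict_factor,
                                     amp_range) {
  dg <- to_birth_lifespan(sublevel_persistence(x))$pairs
  if (nrow(dg) < 2 || !is.finite(eps) || eps <= 0) {
    return(branch_verdict(FALSE, FALSE, list(reason = "degenerate diagram")))
  }
  labels <- dbscan_diagram(dg, eps, min_samples)
  ks <- sort(unique(labels[labels > 0L]))
  if (length(ks) < 2) {
    return(branch_verdict(FALSE, FALSE,
                          list(reason = "fewer than two clusters",
                               n_clusters = length(ks))))
  }
  mean_life <- vapply(ks, function(k) mean(dg[labels == k, 2]), numeric(1))
  sig_k <- ks[which.max(mean_life)]
  noi_k <- ks[which.min(mean_life)]
  sig <- dg[labels == sig_k, , drop = FALSE]
  noi <- dg[labels == noi_k, , drop = FALSE]
  sig_med <- stats::median(sig[, 2])
  noi_max <- max(noi[, 2])
  count_ok <- nrow(sig) >= count_band[1] && nrow(sig) <= count_band[2]
  test <- function(f) {
    count_ok &&
      sig_med >= f * dominance * noi_max &&
      sig_med >= f * amp_fraction * amp_range
  }
  dec <- test(1)
  strict <- test(strict_factor)
  branch_verdict(dec, strict && dec,
                 list(n_signal = nrow(sig), signal_median_life = sig_med,
                      noise_max_life = noi_max, amp_range = amp_range,
                      count_band = count_band))
}

#' Sublevel-set branch of the breathing decision
#'
#' Computes the sublevel-set H0 diagram of the low-pass filtered window,
#' clusters it with DBSCAN (eps from the data-driven diagram spread, minSamp
#' from the minimal breathing rate) and looks for a signal cluster whose
#' point count matches the physiological breathing range for the window
#' length and whose lifespans dominate the noise cluster and a fraction of
#' the window's amplitude range.
#'
#' @param x low-pass filtered phase window.
#' @param criteria a \code{\link{selection_criteria}}.
#' @param fs sampling rate in Hz (sets the window length in seconds).
#' @return a \code{branch_verdict}.
#' @export
breathing_sublevel_branch <- function(x, criteria = selection_criteria(),
                                      fs = 20) {
  cr <- criteria
  if (length(x) < 4 || stats::sd(x) == 0) {
    return(branch_verdict(FALSE, FALSE, list(reason = "degenerate series")))
  }
  window_s <- length(x) / fs
  minsamp <- if (cr$minsamp_mode == "per_window") {
    max(2L, as.integer(floor(cr$breathing_band_bpm[1] * window_s / 60)))
  } else as.integer(cr$breathing_band_bpm[1])
  dg <- to_birth_lifespan(sublevel_persistence(x))$pairs
  eps <- diagram_spread(dg, method = cr$spread_method)
  sublevel_cluster_verdict(
    x, eps, minsamp,
    count_bounds(cr$breathing_band_bpm, window_s),
    cr$lifespan_dominance_factor, cr$signal_amp_fraction, cr$strict_factor,
    amp_range = diff(range(x)))
}

#' Combine the two breathing branch verdicts
#'
#' A bin shows breathing if both branches agree, or if a single branch
#' passes the stricter versions of its criteria.
#'
#' @param vr,sl \code{branch_verdict}s of the Vietoris-Rips and sublevel
#'   branches.
#' @return logical.
#' @export
combine_breathing <- function(vr, sl) {
  (vr$decision && sl$decision) || vr$strict_decision || sl$strict_decision
}

#' Heartbeat bin decision (sublevel-set only)
#'
#' The window must already be band-pass filtered to the heartbeat band.
#' Uses the sublevel-set H0 diagram with minSamp from the lowest expected
#' heart rate and an empirical eps proportional to the window's amplitude
#' range (the data-driven spread is not reliable here); the criteria mirror
#' the breathing sublevel branch with heart-rate count bounds. Single
#' branch, so the lax decision is the final output.
#'
#' @param x band-pass filtered phase window.
#' @param criteria a \code{\link{selection_criteria}}.
#' @param fs sampling rate in Hz.
#' @return a \code{branch_verdict}; use \code{$decision}.
#' @export
heartbeat_selection <- function(x, criteria = selection_criteria(), fs = 20) {
  cr <- criteria
  if (length(x) < 4 || stats::sd(x) == 0) {
    return(branch_verdict(FALSE, FALSE, list(reason = "degenerate series")))
  }
  window_s <- length(x) / fs
  minsamp <- if (cr$minsamp_mode == "per_window") {
    max(2L, as.integer(floor(cr$heartbeat_band_bpm[1] * window_s / 60)))
  } else as.integer(cr$heartbeat_band_bpm[1])
  amp_range <- diff(range(x))
  sublevel_cluster_verdict(
    x, cr$heartbeat_eps_fraction * amp_range, minsamp,
    count_bounds(cr$heartbeat_band_bpm, window_s),
    cr$lifespan_dominance_factor, cr$signal_amp_fraction, cr$strict_factor,
    amp_range = amp_range)
}

#' Run range-bin selection over all bins and windows
#'
#' Applies the breathing (dual-branch) and heartbeat (sublevel-only)
#' pipelines to the unwrapped phase of every restricted bin in every sliding
#' window. Filtering is done once per bin over the full series (the filters
#' are zero-phase), then windows are sliced out. The Vietoris-Rips branch is
#' skipped when the sublevel branch already passed its strict criteria
#' (the combination rule makes its outcome immaterial then).
#'
#' @param m a frame-level, range-restricted \code{\link{range_time_matrix}}.
#' @param grid a \code{\link{window_grid}}.
#' @param criteria a \code{\link{selection_criteria}}.
#' @param verbose print progress per bin.
#' @return an object of class \code{selection_mask}: logical matrices
#'   \code{breathing} and \code{heartbeat} [bin x window], plus
#'   \code{windows} (data.frame of start times), \code{bin_index},
#'   \code{bin_axis}, \code{grid}.
#' @export
select_bins <- function(m, grid = window_grid(),
                        criteria = selection_criteria(), verbose = FALSE) {
  stopifnot(inherits(m, "range_time_matrix"))
  if (m$level != "frame") stop("select_bins expects a frame-level matrix")
  fs <- 1 / (m$time_axis[2] - m$time_axis[1])
  duration <- ncol(m$data) / fs
  win <- make_windows(duration, grid)
  nb <- nrow(m$data); nw <- nrow(win)
  br <- matrix(FALSE, nb, nw)
  hb <- matrix(FALSE, nb, nw)
  wlen <- as.integer(round(grid$window_length * fs))

  for (b in seq_len(nb)) {
    phase <- extract_phase(m, m$bin_index[b])
    lp <- band_filter(phase$values, "breathing", fs = fs,
                      lowpass_hz = criteria$breathing_lowpass_hz)
    bp <- band_filter(phase$values, "heartbeat", fs = fs,
                      band_hz = criteria$heartbeat_band_hz)
    for (w in seq_len(nw)) {
      i0 <- as.integer(round(win$start_s[w] * fs)) + 1L
      idx <- i0:(i0 + wlen - 1L)
      xb <- lp[idx]; xh <- bp[idx]
      res <- tryCatch({
        sl <- breathing_sublevel_branch(xb, criteria, fs)
        if (sl$strict_decision) TRUE else {
          vr <- breathing_vr_branch(xb, criteria)
          combine_breathing(vr, sl)
        }
      }, error = function(e) FALSE)
      br[b, w] <- isTRUE(res)
      hb[b, w] <- isTRUE(tryCatch(
        heartbeat_selection(xh, criteria, fs)$decision,
        error = function(e) FALSE))
    }
    if (verbose) message(sprintf("bin %d/%d done", b, nb))
  }
  structure(list(breathing = br, heartbeat = hb, windows = win,
                 bin_index = m$bin_index, bin_axis = m$bin_axis, grid = grid),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("<selection_mask> %d bins x %d windows; breathing %.1f%%, heartbeat %.1f%% selected\n",
              nrow(x$breathing), ncol(x$breathing),
              100 * mean(x$breathing), 100 * mean(x$heartbeat)))
  invisible(x)
}

#' Sensitivity/specificity of a mask against ground-truth bins
#'
#' @param mask_mat logical [bin x window] matrix.
#' @param bin_index 0-based bin indices of the mask rows.
#' @param true_bins 0-based indices of bins truly carrying the vital sign.
#' @return list with \code{sensitivity} and \code{specificity}.
#' @export
mask_performance <- function(mask_mat, bin_index, true_bins) {
  pos <- bin_index %in% true_bins
  list(sensitivity = mean(mask_mat[pos, , drop = FALSE]),
       specificity = 1 - mean(mask_mat[!pos, , drop = FALSE]))
}
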