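# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation.

# Brute-force sublevel-set H0 pairing via the path-maximum formulation:
# each local minimum i dies at the smallest over lower minima j of the
# maximal value on the path from i to j; the global minimum closes at the
# global maximum. Plateau handling: a flat minimum counts once (leftmost
# sample), ties between equal minima are resolved left-to-right (the
# left-of-two equal minima is the elder).
oracle_sublevel <- function(x) {
  n <- length(x)
  is_min <- logical(n)
  for (i in seq_len(n)) {
    left_higher <- i == 1 || x[i] < x[i - 1]
    # plateau: only the leftmost sample of a flat run can be the minimum
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    right_higher <- j == n || x[j + 1] > x[i]
    flat_left_edge <- i == 1 || x[i - 1] != x[i]
    is_min[i] <- left_higher && right_higher && flat_left_edge
  }
  mins <- which(is_min)
  births <- deaths <- numeric(0)
  for (i in mins) {
    v <- x[i]
    # path max to every index with a strictly lower value, or an equal value
    # to the left (elder by tie-break)
    right_cummax <- cummax(x[i:n])
    left_cummax <- rev(cummax(rev(x[1:i])))
    death <- Inf
    for (j in seq_len(n)) {
      lower <- x[j] < v || (x[j] == v && j < i)
      if (!lower) next
      pm <- if (j > i) right_cummax[j - i + 1] else left_cummax[j]
      death <- min(death, pm)
    }
    if (is.finite(death)) {
      births <- c(births, v); deaths <- c(deaths, death)
    } else {
      births <- c(births, v); deaths <- c(deaths, max(x))  # essential
    }
  }
  cbind(birth = births, death = deaths)
}

# Prim's algorithm MST edge lengths (oracle for Rips H0 deaths)
oracle_mst_edges <- function(pts) {
  dmat <- as.matrix(stats::dist(pts))
  n <- nrow(dmat)
  if (n < 2) return(numeric(0))
  intree <- 1L
  edges <- numeric(0)
  while (length(intree) < n) {
    out <- setdiff(seq_len(n), intree)
    sub <- dmat[intree, out, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    edges <- c(edges, min(sub))
    intree <- c(intree, out[k[2]])
  }
  sort(edges)
}

# --- fixture builders ------------------------------------------------------

fs_frames <- 20

sine_window <- function(rate_bpm = 15, amp = 1, noise = 0.01, dur = 15,
                        fs = fs_frames, seed = 1) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * rate_bpm / 60 * t) + noise * rnorm(length(t))
}

pulse_window <- function(rate_bpm = 70, amp = 0.12, noise = 0.02, dur = 15,
                         fs = fs_frames, seed = 1, sigma = 0.05) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- numeric(length(t))
  for (b in seq(0.3, dur, by = 60 / rate_bpm)) {
    x <- x + exp(-(t - b)^2 / (2 * sigma^2))
  }
  amp * x + noise * rnorm(length(t))
}

noise_window <- function(sd = 0.05, dur = 15, fs = fs_frames, seed = 1) {
  set.seed(seed)
  sd * rnorm(dur * fs)
}

tiny_scene <- function(duration = 60, seed = 1, noise = 0.02) {
  dev <- device_config(n_fast_samples = 80L)  # 40 bins, 0-1.95 m
  segs <- list(
    body_segment(1.0, breathing = list(rate_bpm = 15, amplitude_m = 1e-3)),
    body_segment(0.6, heartbeat = list(rate_bpm = 70, amplitude_m = 5e-5)),
    body_segment(0.8, reflectivity = 0.6))
  list(spec = scene_spec(segs, duration, noise_sigma = noise, seed = seed),
       device = dev)
}
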