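#' Sliding-window grid for selection and rate computation
#'
#' Bin selection runs on short windows (15 s, 5 s step); runs of
#' \code{merge_span} consecutive short windows in which a bin was selected
#' at least \code{merge_quorum} times are merged into rate-computation
#' windows of \code{rate_window_length} seconds. The grid must satisfy
#' \code{(merge_span - 1) * step + window_length == rate_window_length}
#' (9 * 5 + 15 = 60 by default).
#'
#' @param window_length short window length, s.
#' @param step step between window starts, s.
#' @param merge_span number of consecutive short windows considered.
#' @param merge_quorum minimum number of selections within the span.
#' @param rate_window_length merged window length, s.
#' @return an object of class \code{window_grid}.
#' @export
window_grid <- function(window_length = 15, step = 5, merge_span = 10L,
                        merge_quorum = 7L, rate_window_length = 60) {
  stopifnot(window_length > 0, step > 0, merge_span >= 1,
            merge_quorum >= 1, merge_quorum <= merge_span)
  if ((merge_span - 1) * step + window_length != rate_window_length) {
    stop("(merge_span - 1) * step + window_length must equal rate_window_length")
  }
  g <- list(window_length = window_length, step = step,
            merge_span = as.integer(merge_span),
            merge_quorum = as.integer(merge_quorum),
            rate_window_length = rate_window_length)
  class(g) <- "window_grid"
  g
}

#' Enumerate short windows fully inside a recording
#'
#' @param duration recording length, s.
#' @param grid a \code{\link{window_grid}}.
#' @return data.frame with column \code{start_s}.
#' @examples
#' nrow(make_windows(60, window_grid()))  # 10
#' @export
make_windows <- function(duration, grid = window_grid()) {
  if (duration < grid$window_length) {
    stop("recording shorter than one window")
  }
  starts <- seq(0, duration - grid$window_length, by = grid$step)
  data.frame(start_s = starts)
}

#' Merge short-window selections into rate windows by continuity
#'
#' For every run of \code{merge_span} consecutive short windows (advancing
#' on the same step grid) and every bin: the merged window selects the bin
#' iff it was selected at least \code{merge_quorum} times in the run. Runs
#' that would extend beyond the recording are skipped (no padding).
#'
#' @param mask a \code{selection_mask} from \code{\link{select_bins}}, or a
#'   logical [bin x window] matrix.
#' @param grid a \code{\link{window_grid}}.
#' @return for a \code{selection_mask} input, a list of class
#'   \code{merged_mask} with \code{breathing}/\code{heartbeat} matrices
#'   [bin x merged window] and \code{windows}; for a matrix input, the
#'   merged logical matrix.
#' @export
merge_selections <- function(mask, grid = window_grid()) {
  merge_mat <- function(mm) {
    nw <- ncol(mm)
    nr <- nw - grid$merge_span + 1L
    if (nr < 1) return(mm[, 0, drop = FALSE])
    out <- matrix(FALSE, nrow(mm), nr)
    counts <- t(apply(mm, 1, cumsum))
    for (r in seq_len(nr)) {
      hi <- counts[, r + grid$merge_span - 1L, drop = TRUE]
      lo <- if (r == 1) 0 else counts[, r - 1L, drop = TRUE]
      out[, r] <- (hi - lo) >= grid$merge_quorum
    }
    out
  }
  if (is.matrix(mask)) return(merge_mat(mask))
  stopifnot(inherits(mask, "selection_mask"))
  nr <- ncol(mask$breathing) - grid$merge_span + 1L
  starts <- mask$windows$start_s[seq_len(max(nr, 0))]
  structure(list(breathing = merge_mat(mask$breathing),
                 heartbeat = merge_mat(mask$heartbeat),
                 windows = data.frame(start_s = starts),
                 bin_index = mask$bin_index, bin_axis = mask$bin_axis,
                 grid = grid),
            class = "merged_mask")
}
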