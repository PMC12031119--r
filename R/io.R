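#' Write a recording to a plain-text directory layout
#'
#' Layout: \code{header.json} (device fields, level, axes, a config hash),
#' \code{data_re.csv} / \code{data_im.csv} (one row per bin), and optional
#' \code{belt.csv} / \code{ecg.csv} reference traces (\code{time_s, value}).
#' Plain text keeps recordings portable and diffable; matrices are written
#' without headers.
#'
#' @param rec a \code{\link{range_time_matrix}}.
#' @param dir output directory (created if missing).
#' @param belt,ecg optional reference data.frames.
#' @return \code{dir}, invisibly.
#' @export
write_recording <- function(rec, dir, belt = NULL, ecg = NULL) {
  stopifnot(inherits(rec, "range_time_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dev <- rec$device
  header <- list(
    device = dev[setdiff(names(dev), c())],
    level = rec$level,
    time_step_s = rec$time_axis[2] - rec$time_axis[1],
    time_start_s = rec$time_axis[1],
    bin_index = rec$bin_index,
    bin_axis_m = rec$bin_axis,
    n_bins = nrow(rec$data), n_time = ncol(rec$data))
  header$config_hash <- config_hash(header)
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(data.table::as.data.table(Re(rec$data)),
                     file.path(dir, "data_re.csv"), col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(Im(rec$data)),
                     file.path(dir, "data_im.csv"), col.names = FALSE)
  if (!is.null(belt)) data.table::fwrite(belt, file.path(dir, "belt.csv"))
  if (!is.null(ecg)) data.table::fwrite(ecg, file.path(dir, "ecg.csv"))
  invisible(dir)
}

#' Read a recording written by \code{\link{write_recording}}
#'
#' @param dir recording directory.
#' @return list with \code{recording} (a \code{\link{range_time_matrix}})
#'   and, when present, \code{belt} and \code{ecg}.
#' @export
read_recording <- function(dir) {
  hpath <- file.path(dir, "header.json")
  if (!file.exists(hpath)) stop(sprintf("not a recording directory: %s", dir))
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  re <- as.matrix(data.table::fread(file.path(dir, "data_re.csv"),
                                    header = FALSE))
  im <- as.matrix(data.table::fread(file.path(dir, "data_im.csv"),
                                    header = FALSE))
  if (!all(dim(re) == c(header$n_bins, header$n_time))) {
    stop("corrupt recording: matrix dimensions disagree with header")
  }
  d <- header$device
  dev <- device_config(fc = d$fc, B = d$B, T_sweep = d$T_sweep,
                       chirp_interval = d$chirp_interval,
                       chirps_per_frame = d$chirps_per_frame,
                       frame_interval = d$frame_interval,
                       n_fast_samples = d$n_fast_samples)
  m <- matrix(complex(real = re, imaginary = im), nrow = header$n_bins)
  rec <- range_time_matrix(m,
                           header$time_start_s +
                             (seq_len(header$n_time) - 1) * header$time_step_s,
                           header$bin_axis_m, dev, header$level,
                           bin_index = header$bin_index)
  out <- list(recording = rec)
  for (nm in c("belt", "ecg")) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) out[[nm]] <- as.data.frame(data.table::fread(f))
  }
  out
}

# stable short hash of a configuration list (provenance stamping)
config_hash <- function(x) {
  x$config_hash <- NULL
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10)
  raw <- utils::head(charToRaw(paste(s, collapse = "")), 1e6)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %% .Machine$integer.max)
}

#' Write a selection mask as tidy CSV
#'
#' Columns: \code{window_start_s}, \code{bin}, \code{vital},
#' \code{selected}.
#'
#' @param mask a \code{selection_mask} or \code{merged_mask}.
#' @param path output CSV path.
#' @export
write_mask <- function(mask, path) {
  rows <- list()
  for (vital in c("breathing", "heartbeat")) {
    mm <- mask[[vital]]
    rows[[vital]] <- data.frame(
      window_start_s = rep(mask$windows$start_s, each = nrow(mm)),
      bin = rep(mask$bin_index, times = ncol(mm)),
      vital = vital,
      selected = as.vector(mm))
  }
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}

#' Read a mask CSV back into matrices
#' @param path CSV from \code{\link{write_mask}}.
#' @return list with \code{breathing}/\code{heartbeat} matrices,
#'   \code{windows}, \code{bin_index}.
#' @export
read_mask <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  bins <- sort(unique(d$bin))
  starts <- sort(unique(d$window_start_s))
  out <- list(windows = data.frame(start_s = starts),
              bin_index = as.integer(bins))
  for (vital in c("breathing", "heartbeat")) {
    sub <- d[d$vital == vital, ]
    mm <- matrix(FALSE, length(bins), length(starts))
    mm[cbind(match(sub$bin, bins), match(sub$window_start_s, starts))] <-
      sub$selected
    out[[vital]] <- mm
  }
  out
}
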