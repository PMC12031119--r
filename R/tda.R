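#' Persistence diagram
#'
#' @param pairs numeric matrix with columns \code{birth} and \code{death}
#'   (or \code{lifespan}); may have zero rows.
#' @param dim homology dimension (0 or 1).
#' @param representation \code{"birth_death"} or \code{"birth_lifespan"}.
#' @param essential logical vector marking essential classes (death set to
#'   the closing value per the conventions documented in the vignette).
#' @return an object of class \code{persistence_diagram}.
#' @export
persistence_diagram <- function(pairs, dim,
                                representation = c("birth_death", "birth_lifespan"),
                                essential = rep(FALSE, nrow(pairs))) {
  representation <- match.arg(representation)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns")
  colnames(pairs) <- if (representation == "birth_death")
    c("birth", "death") else c("birth", "lifespan")
  if (representation == "birth_death" && nrow(pairs) &&
      any(pairs[, 2] < pairs[, 1] - 1e-12)) {
    stop("death must be >= birth for all pairs")
  }
  d <- list(pairs = pairs, dim = as.integer(dim),
            representation = representation,
            essential = as.logical(essential))
  class(d) <- "persistence_diagram"
  d
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> H%d, %d pairs (%s)\n",
              x$dim, nrow(x$pairs), x$representation))
  invisible(x)
}

#' Time-delay embedding of a scalar series
#'
#' Maps \code{x} to the point cloud with one point
#' \code{(x(t), x(t - tau), ..., x(t - (m-1) tau))} per valid t (uniform
#' embedding). The number of points is \code{length(x) - (m-1) tau}.
#'
#' @param x numeric series.
#' @param tau delay in samples (default 10, i.e. 0.5 s at the 20 Hz frame
#'   rate).
#' @param m embedding dimension (default 3).
#' @return numeric matrix [n_points x m].
#' @examples
#' time_delay_embed(0:4, tau = 1, m = 2)
#' @export
time_delay_embed <- function(x, tau = 10L, m = 3L) {
  tau <- as.integer(tau); m <- as.integer(m)
  stopifnot(tau >= 1, m >= 2)
  n <- length(x) - (m - 1L) * tau
  if (n < 1) stop("series too short for this embedding (need length > (m-1)*tau)")
  # column k+1 holds x(t - k*tau); rows run over valid t
  out <- vapply(seq_len(m) - 1L,
                function(k) x[seq_len(n) + (m - 1L) * tau - k * tau],
                numeric(n))
  if (n == 1) out <- matrix(out, nrow = 1)
  dimnames(out) <- NULL
  out
}

#' Sublevel-set H0 persistence of a 1-D series
#'
#' Sweeps a level upward through the series: each local minimum births a
#' connected component, components merge at local maxima under the elder
#' rule (the younger, i.e. shallower, component dies), and the essential
#' component is closed at the global maximum. Plateaus are processed
#' left-to-right, so a flat local minimum births exactly one component.
#'
#' @param x finite numeric series of length >= 2.
#' @return a \code{\link{persistence_diagram}} (H0, birth-death) whose
#'   \code{essential} flag marks the global-minimum class.
#' @export
sublevel_persistence <- function(x) {
  if (any(is.na(x))) stop("series contains NA/NaN")
  p <- cpp_sublevel_h0(as.numeric(x))
  persistence_diagram(p[, 1:2, drop = FALSE], dim = 0L,
                      essential = p[, 3] > 0)
}

#' Vietoris-Rips persistence of a point cloud
#'
#' Computes H0 (and H1 for \code{maxdim = 1}) persistence of the Euclidean
#' Rips filtration. Scale convention: distances (an edge enters the
#' filtration at the pairwise distance, i.e. twice the usual ball radius r), matching
#' common software output. The H0 essential class (infinite death) is
#' reported with \code{death = Inf} and flagged; criteria downstream use the
#' largest finite H0 death.
#'
#' @param cloud numeric matrix [points x coordinates].
#' @param maxdim 0 or 1.
#' @param max_points clouds larger than this must be subsampled first
#'   (performance guard); see \code{\link{subsample_cloud}}.
#' @return list with \code{h0} and \code{h1} persistence diagrams and
#'   \code{enclosing_radius}.
#' @export
rips_persistence <- function(cloud, maxdim = 1L, max_points = 1e4) {
  cloud <- as.matrix(cloud)
  if (!all(is.finite(cloud))) stop("point cloud contains non-finite values")
  if (nrow(cloud) > max_points) {
    stop("point cloud exceeds max_points; subsample first (subsample_cloud)")
  }
  stopifnot(maxdim %in% c(0L, 1L))
  res <- cpp_rips(cloud, as.integer(maxdim))
  h0p <- res$h0
  h0 <- persistence_diagram(
    rbind(h0p, c(0, Inf)), dim = 0L,
    essential = c(rep(FALSE, nrow(h0p)), TRUE))
  h1 <- persistence_diagram(res$h1, dim = 1L)
  list(h0 = h0, h1 = h1,
       enclosing_radius = if (!is.null(res$enclosing_radius))
         res$enclosing_radius else NA_real_)
}

#' Farthest-point subsampling of a point cloud
#'
#' Deterministic maxmin subsampling preserving the cloud's geometry (the
#' optimization route for making Rips filtrations affordable on long
#' windows).
#'
#' @param cloud numeric matrix [points x coordinates].
#' @param k target number of points.
#' @return the subsampled matrix (all points if \code{k >= nrow}).
#' @export
subsample_cloud <- function(cloud, k) {
  cloud <- as.matrix(cloud)
  idx <- cpp_farthest_point_sample(cloud, as.integer(k))
  cloud[sort(idx), , drop = FALSE]
}

#' Convert a diagram between birth-death and birth-lifespan form
#'
#' \code{to_birth_lifespan} maps each pair (b, d) to (b, d - b);
#' applying it to a birth-lifespan diagram inverts the transform.
#'
#' @param diagram a \code{\link{persistence_diagram}}.
#' @return the transformed \code{\link{persistence_diagram}}.
#' @export
to_birth_lifespan <- function(diagram) {
  stopifnot(inherits(diagram, "persistence_diagram"))
  p <- diagram$pairs
  if (diagram$representation == "birth_death") {
    out <- cbind(p[, 1], p[, 2] - p[, 1])
    persistence_diagram(out, diagram$dim, "birth_lifespan",
                        essential = diagram$essential)
  } else {
    out <- cbind(p[, 1], p[, 1] + p[, 2])
    persistence_diagram(out, diagram$dim, "birth_death",
                        essential = diagram$essential)
  }
}

#' Data-driven spread of a set of diagram points
#'
#' The scale at which a secondary Rips filtration on the diagram points
#' connects them into one component: the largest finite H0 death, i.e. the
#' longest edge of the Euclidean minimum spanning tree (single-linkage
#' connection scale). \code{method = "diameter"} returns the plain cloud
#' diameter instead (for sensitivity analysis; the default is the
#' connection-scale reading).
#'
#' @param points numeric matrix [n x 2] of diagram points.
#' @param method \code{"connection"} or \code{"diameter"}.
#' @return the spread (scalar), or \code{NA} if fewer than 2 points
#'   ("no spread"; callers must fall back).
#' @export
diagram_spread <- function(points, method = c("connection", "diameter")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  if (nrow(points) < 2) return(NA_real_)
  if (method == "diameter") {
    return(max(stats::dist(points)))
  }
  res <- cpp_rips(points, 0L)
  max(res$h0[, 2])
}

#' Write a persistence diagram to CSV
#'
#' Columns: \code{dim}, \code{birth}, \code{death}, \code{lifespan},
#' \code{essential}. Accepts diagrams in either representation.
#'
#' @param diagram a \code{\link{persistence_diagram}} or a list of them.
#' @param path output CSV path.
#' @export
write_diagram <- function(diagram, path) {
  if (inherits(diagram, "persistence_diagram")) diagram <- list(diagram)
  rows <- lapply(diagram, function(d) {
    bd <- if (d$representation == "birth_death") d else to_birth_lifespan(d)
    p <- bd$pairs
    data.frame(dim = rep(d$dim, nrow(p)), birth = p[, 1], death = p[, 2],
               lifespan = p[, 2] - p[, 1],
               essential = bd$essential)
  })
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}
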