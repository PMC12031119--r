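#' DBSCAN clustering of persistence-diagram points
#'
#' Plain density-based clustering (Euclidean metric, O(n^2), which is ample
#' for diagram-sized inputs). Conventions, chosen so that an eps derived
#' from \code{\link{diagram_spread}} (the scale at which everything
#' connects) still isolates outliers:
#' \itemize{
#'   \item neighborhoods use the strict inequality \code{dist < eps}
#'     (coincident points are always neighbors);
#'   \item \code{min_samples} counts the point itself (so
#'     \code{min_samples = 2} means "has at least one neighbor").
#' }
#' Points labeled 0 are noise from DBSCAN's perspective; in the
#' Vietoris-Rips branch these are the informative outliers.
#'
#' @param points numeric matrix [n x d].
#' @param eps neighborhood radius.
#' @param min_samples minimum neighborhood size (including the point) for a
#'   core point.
#' @return integer vector of labels: 0 = outlier/noise, 1..k = clusters.
#' @export
dbscan_diagram <- function(points, eps, min_samples = 2L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) return(integer(0))
  if (!is.finite(eps) || eps < 0) stop("eps must be finite and non-negative")
  dmat <- as.matrix(stats::dist(points))
  nbr <- dmat < eps | dmat == 0
  deg <- rowSums(nbr)                 # includes self (diagonal is 0 < eps or == 0)
  core <- deg >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (core[q]) {
        reach <- which(nbr[q, ] & labels == 0L)
        labels[reach] <- cl
        queue <- c(queue, reach[core[reach]])
      }
    }
  }
  labels
}
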