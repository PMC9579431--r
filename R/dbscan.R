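#' Density-based clustering (DBSCAN)
#'
#' Standard DBSCAN semantics on Euclidean distances: a point is a core
#' point iff at least `min_pts` points (itself included) lie within `eps`;
#' clusters are the connected components of core points under
#' eps-reachability; border points join the cluster of the first core point
#' (in index order) that reaches them; remaining points are noise
#' (label 0). Deterministic: points are visited in index order.
#'
#' @param points numeric matrix (rows = points) or data.frame.
#' @param eps neighborhood radius.
#' @param min_pts core-point threshold (default 5).
#' @return integer vector of cluster labels, 0 = noise; attribute `core`
#'   marks core points.
#' @export
dbscan_cluster <- function(points, eps = 1, min_pts = 5) {
  X <- as.matrix(points)
  stopifnot(all(is.finite(X)), eps > 0, min_pts >= 1)
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)                 # 0 = unassigned / noise
  # clusters = connected components of core points under eps-reachability
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      cand <- nb[[j]][core[nb[[j]]] & labels[nb[[j]]] == 0L]
      labels[cand] <- cl
      queue <- c(queue, cand)
    }
  }
  # border points join the cluster of their first core neighbor in index
  # order; points with no core neighbor are noise
  for (i in which(!core)) {
    cands <- nb[[i]][core[nb[[i]]]]
    if (length(cands)) labels[i] <- labels[cands[1]]
  }
  attr(labels, "core") <- core
  labels
}
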