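#' UMAP embedding of an attribution matrix
#'
#' Self-contained implementation of Uniform Manifold Approximation and
#' Projection for small tabular inputs (hundreds of rows): exact k-nearest
#' neighbors on the Euclidean metric, smooth-kNN bandwidth calibration to
#' log2(k) effective neighbors, fuzzy simplicial-set union, spectral
#' initialisation from the normalized graph Laplacian, and layout
#' optimisation of the cross-entropy objective by gradient descent over the
#' edge set with uniform negative sampling. Deterministic given `seed`.
#'
#' @param X numeric matrix or data.frame (rows = patients).
#' @param n_neighbors neighborhood size (default 15).
#' @param min_dist minimum separation in the embedding (default 0.1).
#' @param n_components embedding dimension (default 2).
#' @param n_epochs optimisation epochs (default 500, the reference small-data
#'   setting).
#' @param learning_rate initial learning rate (decays linearly to 0).
#' @param negative_sample_rate negative samples per positive edge.
#' @param seed integer seed.
#' @return n x n_components coordinate matrix.
#' @export
umap_embed <- function(X, n_neighbors = 15, min_dist = 0.1,
                       n_components = 2, n_epochs = 500,
                       learning_rate = 1, negative_sample_rate = 5,
                       seed = 42L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(all(is.finite(X)), n_neighbors >= 2, min_dist > 0)
  if (n < n_neighbors + 1)
    stop("umap_embed: need at least n_neighbors + 1 rows")
  k <- min(n_neighbors, n - 1)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))

  ## ---- fuzzy simplicial set ----
  d <- as.matrix(stats::dist(X))
  P <- matrix(0, n, n)
  target <- log2(k)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    ord <- order(di)[seq_len(k)]
    knn_d <- di[ord]
    idx <- (seq_len(n)[-i])[ord]
    rho <- min(knn_d[knn_d > 0], Inf)
    if (!is.finite(rho)) rho <- 0
    lo <- 0; hi <- Inf; sigma <- 1
    for (it in 1:64) {
      val <- sum(exp(-pmax(knn_d - rho, 0) / sigma))
      if (abs(val - target) < 1e-5) break
      if (val > target) { hi <- sigma; sigma <- (lo + hi) / 2 }
      else { lo <- sigma; sigma <- if (is.finite(hi)) (lo + hi) / 2 else sigma * 2 }
    }
    P[i, idx] <- exp(-pmax(knn_d - rho, 0) / sigma)
  }
  P <- P + t(P) - P * t(P)                 # fuzzy union

  ## ---- output-space kernel parameters from min_dist ----
  ab <- fit_umap_curve(min_dist)
  a <- ab[1]; b <- ab[2]

  ## ---- spectral initialisation ----
  Y <- spectral_init(P, n_components)
  Y <- Y / max(abs(Y)) * 10
  Y <- Y + matrix(stats::rnorm(n * n_components, sd = 1e-4), n)

  ## ---- layout optimisation (sequential SGD over the edge set) ----
  # directed edges (both orientations), visited with frequency
  # proportional to membership weight; edges too weak to be sampled within
  # n_epochs are dropped, as in the reference implementation
  eidx <- which(P > 0, arr.ind = TRUE)
  w <- P[eidx]
  keep <- w >= max(w) / n_epochs
  eidx <- eidx[keep, , drop = FALSE]
  w <- w[keep]
  epochs_per_sample <- max(w) / w
  Y <- .umap_optimize_layout(Y, eidx[, 1] - 1L, eidx[, 2] - 1L,
                             epochs_per_sample, as.integer(n_epochs),
                             a, b, learning_rate, negative_sample_rate,
                             1.0)
  dimnames(Y) <- list(rownames(X), paste0("umap", seq_len(n_components)))
  Y
}

# Least-squares fit of 1/(1 + a x^(2b)) to the target membership curve
# (1 for x < min_dist, exp(-(x - min_dist)) beyond), as in the reference
# implementation.
fit_umap_curve <- function(min_dist, spread = 1) {
  x <- seq(0, spread * 3, length.out = 300)
  y <- ifelse(x < min_dist, 1, exp(-(x - min_dist) / spread))
  fit <- stats::nls(y ~ 1 / (1 + a * x^(2 * b)),
                    start = list(a = 1.5, b = 1),
                    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  stats::coef(fit)
}

# Spectral layout: eigenvectors of the symmetric normalized Laplacian of
# the fuzzy graph for the smallest non-trivial eigenvalues. Falls back to
# PCA when the graph is disconnected enough to make the eigenproblem
# degenerate.
spectral_init <- function(P, n_components) {
  n <- nrow(P)
  deg <- rowSums(P)
  if (any(deg <= 0)) return(pca_init(P, n_components))
  Dinv <- 1 / sqrt(deg)
  L <- diag(n) - (Dinv * P) %*% diag(Dinv)
  eig <- tryCatch(eigen(L, symmetric = TRUE), error = function(e) NULL)
  if (is.null(eig)) return(pca_init(P, n_components))
  ord <- order(eig$values)
  eig$vectors[, ord[seq(2, 1 + n_components)], drop = FALSE]
}

pca_init <- function(M, n_components) {
  pc <- stats::prcomp(M, rank. = n_components)
  pc$x[, seq_len(n_components), drop = FALSE]
}
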