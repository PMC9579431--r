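#' Linear-SVM validation of cluster separability
#'
#' For each non-noise cluster, trains a one-vs-rest linear support-vector
#' machine on a stratified 0.8:0.2 train/test split of the embedding. The
#' cost parameter is tuned on the training split by repeated
#' cross-validation (3 repeats of 10 folds by default) maximizing the AUC
#' over a log-spaced grid, and the tuned model is scored on bootstrap
#' resamples (n = 2000 by default) of the held-out test split.
#'
#' @param points embedding coordinates (matrix or data.frame).
#' @param labels integer cluster labels (0 = noise, excluded).
#' @param split training fraction (default 0.8).
#' @param repeats,folds CV scheme for cost tuning.
#' @param n_boot bootstrap resamples of the test split.
#' @param cost_grid candidate costs.
#' @param seed integer seed.
#' @return data.frame of class `svm_validation`: per cluster the tuned
#'   cost, mean and sd of the bootstrap AUC distribution; the distributions
#'   themselves in attribute `boot_auc`.
#' @export
svm_validate <- function(points, labels, split = 0.8, repeats = 3,
                         folds = 10, n_boot = 2000,
                         cost_grid = 2^seq(-5, 3, by = 2), seed = 1L) {
  X <- as.matrix(points)
  keep <- labels != 0
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  clusters <- sort(unique(labels))
  if (length(clusters) < 2)
    stop("svm_validate: need at least 2 non-noise clusters")
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))

  # stratified split so every cluster appears on both sides
  train_idx <- unlist(lapply(clusters, function(cl) {
    ii <- which(labels == cl)
    take <- max(1, round(split * length(ii)))
    sample(ii, take)
  }))
  test_idx <- setdiff(seq_along(labels), train_idx)
  if (!all(clusters %in% labels[train_idx]) ||
      !all(clusters %in% labels[test_idx]))
    stop("svm_validate: a cluster is absent from one side of the split")

  boot_auc <- list()
  rows <- lapply(clusters, function(cl) {
    ytr <- factor(as.integer(labels[train_idx] == cl), levels = c(0, 1))
    yte <- as.integer(labels[test_idx] == cl)
    Xtr <- X[train_idx, , drop = FALSE]
    Xte <- X[test_idx, , drop = FALSE]
    cv_auc <- vapply(cost_grid, function(cost) {
      aucs <- c()
      for (r in seq_len(repeats)) {
        fold_id <- sample(rep_len(seq_len(folds), length(ytr)))
        for (f in seq_len(folds)) {
          te <- fold_id == f
          if (length(unique(ytr[!te])) < 2) next
          hold <- as.integer(as.character(ytr[te]))
          if (length(unique(hold)) < 2) next
          fit <- e1071::svm(Xtr[!te, , drop = FALSE], ytr[!te],
                            kernel = "linear", cost = cost, scale = FALSE)
          dv <- svm_decision(fit, Xtr[te, , drop = FALSE])
          aucs <- c(aucs, auc_rank(dv, hold))
        }
      }
      mean(aucs)
    }, numeric(1))
    best_cost <- cost_grid[which.max(cv_auc)]
    fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = best_cost,
                      scale = FALSE)
    dv_te <- svm_decision(fit, Xte)
    boots <- vapply(seq_len(n_boot), function(b) {
      repeat {
        ii <- sample.int(length(yte), replace = TRUE)
        if (length(unique(yte[ii])) == 2) break
      }
      auc_rank(dv_te[ii], yte[ii])
    }, numeric(1))
    boot_auc[[as.character(cl)]] <<- boots
    data.frame(cluster = cl, cost = best_cost,
               auc_mean = mean(boots), auc_sd = stats::sd(boots))
  })
  out <- do.call(rbind, rows)
  attr(out, "boot_auc") <- boot_auc
  class(out) <- c("svm_validation", "data.frame")
  out
}

# Decision values oriented so larger = more likely the "1" (cluster) class;
# e1071 orients toward the first class named in the decision-value column.
svm_decision <- function(fit, X) {
  dv_attr <- attr(stats::predict(fit, X, decision.values = TRUE),
                  "decision.values")
  dv <- dv_attr[, 1]
  first <- strsplit(colnames(dv_attr)[1], "/")[[1]][1]
  if (first != "1") dv <- -dv
  dv
}

#' Per-cluster attribution profiles and defining risk factors
#'
#' Summarizes a Shapley matrix by cluster: mean contribution and mean
#' absolute contribution per feature, each cluster's defining factor (the
#' feature whose cluster-mean contribution deviates most, in absolute
#' value, from the overall mean contribution) with a ranked factor list,
#' and per-feature discriminativeness (variance of cluster means).
#'
#' @param sm a `shap_matrix`.
#' @param labels cluster labels aligned to the matrix rows (0 = noise,
#'   excluded from profiles).
#' @return list of class `cluster_profile`: `mean_phi` and `mean_abs_phi`
#'   (cluster x feature matrices), `defining_factor` (named character),
#'   `ranking` (list of per-cluster rankings), `discriminativeness`
#'   (named numeric).
#' @export
cluster_profiles <- function(sm, labels) {
  stopifnot(inherits(sm, "shap_matrix"),
            length(labels) == nrow(sm$phi))
  keep <- labels != 0
  phi <- sm$phi[keep, , drop = FALSE]
  labs <- labels[keep]
  clusters <- sort(unique(labs))
  if (any(tabulate(match(labs, clusters)) == 0))
    stop("cluster_profiles: empty cluster")
  mean_phi <- matrix(NA_real_, length(clusters), ncol(phi),
                     dimnames = list(clusters, colnames(phi)))
  mean_abs <- mean_phi
  for (i in seq_along(clusters)) {
    block <- phi[labs == clusters[i], , drop = FALSE]
    mean_phi[i, ] <- colMeans(block)
    mean_abs[i, ] <- colMeans(abs(block))
  }
  overall <- colMeans(phi)
  dev <- sweep(mean_phi, 2, overall)
  if (length(clusters) == 1) dev <- abs(mean_phi)  # degenerate: largest |mean phi|
  ranking <- lapply(seq_along(clusters), function(i)
    colnames(phi)[order(abs(dev[i, ]), decreasing = TRUE)])
  names(ranking) <- clusters
  defining <- vapply(ranking, `[`, character(1), 1)
  disc <- apply(mean_phi, 2, stats::var)
  if (length(clusters) == 1) disc[] <- 0
  structure(list(mean_phi = mean_phi, mean_abs_phi = mean_abs,
                 defining_factor = defining, ranking = ranking,
                 discriminativeness = disc, clusters = clusters),
            class = "cluster_profile")
}
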