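#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' Computes the AUC of a continuous score against a binary label using mean
#' ranks, which applies the midrank correction for tied scores. This is the
#' single AUC primitive used throughout the package (model evaluation, SVM
#' validation, permutation importance) so that tie handling is uniform.
#'
#' @param score numeric vector of scores (higher = more likely positive).
#' @param y binary vector (0/1 or logical) of the same length.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(score, y) {
  y <- as.integer(as.logical(y))
  stopifnot(length(score) == length(y), all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("auc_rank: both classes must be present")
  r <- rank(score)                      # midranks for ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified bootstrap percentile interval for the AUC
#'
#' Resamples positives and negatives separately (preserving prevalence) and
#' returns the percentile interval of the AUC distribution.
#'
#' @param score,y as in [auc_rank()].
#' @param n_boot number of bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list with `auc`, `lower`, `upper`, `boot` (the resampled AUCs).
#' @export
auc_boot_ci <- function(score, y, n_boot = 2000, conf = 0.95, seed = 1L) {
  y <- as.integer(as.logical(y))
  idx1 <- which(y == 1L)
  idx0 <- which(y == 0L)
  est <- auc_rank(score, y)
  rng <- local_rng(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    i1 <- idx1[sample.int(length(idx1), replace = TRUE)]
    i0 <- idx0[sample.int(length(idx0), replace = TRUE)]
    ii <- c(i1, i0)
    auc_rank(score[ii], y[ii])
  }, numeric(1))
  restore_rng(rng)
  a <- (1 - conf) / 2
  qs <- stats::quantile(boot, c(a, 1 - a), names = FALSE)
  list(auc = est, lower = qs[1], upper = qs[2], boot = boot)
}

# Scoped RNG: seed inside a function without clobbering the caller's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derive a stage-specific child seed from a master seed, kept below 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12347L) %% 2147483587L
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors; 1 for identical
#' partitions (up to renaming), ~0 for independent ones. Used to score
#' recovery of planted phenotype groups by the clustering stage.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
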