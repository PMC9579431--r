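#' Posterior probability of outcomes per cluster with bootstrap inference
#'
#' With cluster membership as the single categorical predictor, the
#' Naive-Bayes posterior of a categorical outcome reduces to the
#' Laplace-smoothed conditional frequency P(outcome | cluster); the default
#' smoothing alpha = 0 makes it the raw conditional frequency.
#' Percentile confidence intervals and two-sided pairwise p-values for
#' differences between clusters come from patient-level bootstrap
#' resampling (n = 2000 by default); a resample leaving a cluster empty is
#' redrawn up to 10 times, then dropped.
#'
#' @param labels cluster labels (0 = noise, excluded).
#' @param outcome categorical outcome vector aligned with `labels`.
#' @param n_boot bootstrap resamples.
#' @param alpha Laplace smoothing constant.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list of class `posterior_report`: `posterior` (cluster x level
#'   matrix), `ci_lower`, `ci_upper` (same shape), `pairwise` (data.frame
#'   of two-sided bootstrap p per cluster pair and outcome level),
#'   `n_dropped` (replicates dropped after redraw failures).
#' @export
posterior_by_cluster <- function(labels, outcome, n_boot = 2000, alpha = 0,
                                 conf = 0.95, seed = 1L) {
  keep <- labels != 0
  labels <- labels[keep]
  outcome <- as.character(outcome[keep])
  clusters <- sort(unique(labels))
  levels_ <- sort(unique(outcome))
  if (length(clusters) < 2) stop("posterior_by_cluster: need >= 2 clusters")
  post_fun <- function(lab, out) {
    t(vapply(clusters, function(cl) {
      cnt <- vapply(levels_, function(lv)
        sum(lab == cl & out == lv), numeric(1))
      (cnt + alpha) / (sum(cnt) + alpha * length(levels_))
    }, numeric(length(levels_))))
  }
  est <- post_fun(labels, outcome)
  dimnames(est) <- list(clusters, levels_)

  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  n <- length(labels)
  boot <- array(NA_real_, c(n_boot, length(clusters), length(levels_)))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    ok <- FALSE
    for (try in 1:10) {
      ii <- sample.int(n, replace = TRUE)
      if (all(clusters %in% labels[ii])) { ok <- TRUE; break }
    }
    if (!ok) { dropped <- dropped + 1L; next }
    boot[b, , ] <- post_fun(labels[ii], outcome[ii])
  }
  a2 <- (1 - conf) / 2
  ci_lo <- apply(boot, c(2, 3), stats::quantile, probs = a2, na.rm = TRUE)
  ci_hi <- apply(boot, c(2, 3), stats::quantile, probs = 1 - a2, na.rm = TRUE)
  dimnames(ci_lo) <- dimnames(ci_hi) <- dimnames(est)

  pairs <- utils::combn(seq_along(clusters), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    do.call(rbind, lapply(seq_along(levels_), function(l) {
      diff_b <- boot[, i, l] - boot[, j, l]
      diff_b <- diff_b[!is.na(diff_b)]
      p_lo <- mean(diff_b <= 0)
      p_hi <- mean(diff_b >= 0)
      data.frame(cluster_a = clusters[i], cluster_b = clusters[j],
                 level = levels_[l], diff = est[i, l] - est[j, l],
                 p = min(1, 2 * min(p_lo, p_hi)))
    }))
  }))
  structure(list(posterior = est, ci_lower = ci_lo, ci_upper = ci_hi,
                 pairwise = pw, n_dropped = dropped),
            class = "posterior_report")
}

#' Cox proportional-hazards comparison between clusters
#'
#' Fits a proportional-hazards model with cluster indicators (Breslow tie
#' handling, Newton maximization of the partial likelihood, delegated to
#' the survival package) and reports the hazard ratio, Wald 95% CI and
#' p-value of each cluster against the reference.
#'
#' @param time event/censoring times (> 0).
#' @param event binary event indicator.
#' @param cluster cluster labels (0 = noise, excluded).
#' @param reference reference cluster (default: first in sort order).
#' @return data.frame of class `cox_result`: contrast, hr, lower, upper, p.
#' @export
cox_compare <- function(time, event, cluster, reference = NULL) {
  keep <- cluster != 0
  time <- time[keep]; event <- as.integer(event[keep])
  cluster <- cluster[keep]
  stopifnot(all(time > 0), all(event %in% 0:1))
  if (sum(event) == 0) stop("cox_compare: no events")
  clusters <- sort(unique(cluster))
  if (length(clusters) < 2) stop("cox_compare: need >= 2 clusters")
  if (is.null(reference)) reference <- clusters[1]
  f <- stats::relevel(factor(cluster), ref = as.character(reference))
  all_censored <- vapply(clusters, function(cl)
    sum(event[cluster == cl]) == 0, logical(1))
  if (any(all_censored))
    warning("cox_compare: cluster(s) with all-censored times; ",
            "estimates may be unstable: ",
            paste(clusters[all_censored], collapse = ", "))
  fit <- survival::coxph(survival::Surv(time, event) ~ f, ties = "breslow")
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  out <- data.frame(
    contrast = paste0(sub("^f", "", rownames(co)), " vs ", reference),
    hr = co[, "exp(coef)"], lower = ci[, "lower .95"],
    upper = ci[, "upper .95"], p = co[, "Pr(>|z|)"],
    row.names = NULL)
  class(out) <- c("cox_result", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Predicted hospital-death risk vs AKI severity, per cluster
#'
#' Per cluster, a logistic regression of death on the restricted cubic
#' spline basis of the peak-to-baseline creatinine ratio, evaluated over a
#' common ratio grid with pointwise Wald CIs, plus a likelihood-ratio test
#' of the ratio effect against the intercept-only model. Clusters with
#' fewer than `min_n` patients or a single-class outcome are suppressed
#' with a warning.
#'
#' @param cluster cluster labels (0 = noise, excluded).
#' @param ratio peak/baseline creatinine ratio per patient (>= 1).
#' @param death binary hospital-death indicator.
#' @param grid ratio grid (default 40 points over the observed range).
#' @param min_n minimum cluster size for a curve.
#' @return list of class `severity_mortality`: per retained cluster a
#'   data.frame (grid, prob, lower, upper) and an `lrt` data.frame
#'   (cluster, statistic, df, p); suppressed clusters listed in
#'   `suppressed`.
#' @export
severity_mortality_curve <- function(cluster, ratio, death, grid = NULL,
                                     min_n = 10) {
  keep <- cluster != 0
  cluster <- cluster[keep]; ratio <- ratio[keep]
  death <- as.integer(death[keep])
  stopifnot(all(ratio >= 1))
  if (is.null(grid)) grid <- seq(min(ratio), max(ratio), length.out = 40)
  curves <- list()
  lrt <- data.frame()
  suppressed <- c()
  for (cl in sort(unique(cluster))) {
    ii <- cluster == cl
    if (sum(ii) < min_n || length(unique(death[ii])) < 2) {
      warning("severity_mortality_curve: curve suppressed for cluster ", cl)
      suppressed <- c(suppressed, cl)
      next
    }
    x <- ratio[ii]; y <- death[ii]
    B <- tryCatch(rcs_basis(x), error = function(e) NULL)
    if (is.null(B)) {  # degenerate ratio support: linear logit fallback
      B <- cbind(lin = x)
      knots <- NULL
    } else knots <- attr(B, "knots")
    fit <- suppressWarnings(stats::glm(y ~ B, family = stats::binomial()))
    null <- stats::glm(y ~ 1, family = stats::binomial())
    stat <- null$deviance - fit$deviance
    lrt <- rbind(lrt, data.frame(cluster = cl, statistic = stat,
                                 df = ncol(B),
                                 p = stats::pchisq(stat, ncol(B),
                                                   lower.tail = FALSE)))
    Bg <- if (is.null(knots)) cbind(lin = grid)
          else rcs_basis(grid, knots = knots)
    Xg <- cbind(1, Bg)
    eta <- drop(Xg %*% stats::coef(fit))
    V <- stats::vcov(fit)
    se <- sqrt(rowSums((Xg %*% V) * Xg))
    curves[[as.character(cl)]] <- data.frame(
      grid = grid, prob = stats::plogis(eta),
      lower = stats::plogis(eta - 1.96 * se),
      upper = stats::plogis(eta + 1.96 * se))
  }
  structure(list(curves = curves, lrt = lrt, suppressed = suppressed),
            class = "severity_mortality")
}
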