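#' Local-regression additive logistic fit (LOESS sensitivity model)
#'
#' Alternative smoother for the nonlinear sensitivity analysis: a local
#' scoring algorithm where, inside each IRLS step, the additive predictor is
#' rebuilt by backfitting — linear terms by weighted least squares, each
#' smooth term by a locally-weighted linear scatterplot smoother (LOESS) of
#' the partial working residuals. Exposes the same prediction and
#' partial-dependence contract as [fit_additive_model()] so the two fits
#' can be overlaid.
#'
#' @param data covariate data.frame (complete).
#' @param y binary outcome.
#' @param smooth_vars covariates smoothed by LOESS.
#' @param linear_vars covariates entering linearly.
#' @param span LOESS span (fraction of points in each local neighborhood).
#' @param degree local polynomial degree (1 = local linear).
#' @param max_iter outer IRLS iterations.
#' @param backfit_iter inner backfitting sweeps per IRLS step.
#' @return object of class `aki_loess_gam`.
#' @export
loess_refit <- function(data, y, smooth_vars = character(),
                        linear_vars = character(), span = 0.75, degree = 1,
                        max_iter = 25, backfit_iter = 5) {
  y <- as.integer(as.logical(y))
  n <- length(y)
  if (span * n < degree + 2)
    stop("loess_refit: span too small for local neighborhoods")
  Xl <- if (length(linear_vars))
    as.matrix(data[linear_vars]) else matrix(0, n, 0)
  fs <- matrix(0, n, length(smooth_vars),
               dimnames = list(NULL, smooth_vars))
  beta <- rep(0, ncol(Xl) + 1)
  eta <- rep(stats::qlogis(pmin(pmax(mean(y), 1e-3), 1 - 1e-3)), n)
  loess_fits <- vector("list", length(smooth_vars))
  names(loess_fits) <- smooth_vars
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / w
    for (bf in seq_len(backfit_iter)) {
      # linear block (with intercept) on residual from smooths
      r_lin <- z - rowSums(fs)
      fit_lin <- stats::lm.wfit(cbind(1, Xl), r_lin, w)
      beta <- fit_lin$coefficients
      lin_part <- drop(cbind(1, Xl) %*% beta)
      for (j in seq_along(smooth_vars)) {
        r_j <- z - lin_part - rowSums(fs[, -j, drop = FALSE])
        lf <- stats::loess(r_j ~ xx, data = data.frame(xx = data[[smooth_vars[j]]], r_j = r_j),
                           weights = w, span = span, degree = degree,
                           surface = "direct",
                           control = stats::loess.control(iterations = 1))
        fj <- stats::fitted(lf)
        fj <- fj - stats::weighted.mean(fj, w)   # center for identifiability
        fs[, j] <- fj
        loess_fits[[j]] <- lf
      }
    }
    eta <- drop(cbind(1, Xl) %*% beta) + rowSums(fs)
    mu <- stats::plogis(eta)
    dev <- -2 * sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
    if (abs(dev_old - dev) < 1e-8 * (abs(dev) + 1)) break
    dev_old <- dev
  }
  # per-smooth centering offsets so prediction reuses the raw loess surfaces
  offsets <- vapply(seq_along(smooth_vars), function(j) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    stats::weighted.mean(stats::fitted(loess_fits[[j]]), w)
  }, numeric(1))
  structure(list(beta = beta, loess = loess_fits, offsets = offsets,
                 smooth_vars = smooth_vars, linear_vars = linear_vars,
                 vars = c(smooth_vars, linear_vars), deviance = dev,
                 span = span, degree = degree),
            class = "aki_loess_gam")
}

#' @rdname loess_refit
#' @param object fitted `aki_loess_gam`.
#' @param newdata data.frame of covariates.
#' @param type "response" or "link".
#' @param ... unused.
#' @export
predict.aki_loess_gam <- function(object, newdata,
                                  type = c("response", "link"), ...) {
  type <- match.arg(type)
  n <- nrow(newdata)
  Xl <- if (length(object$linear_vars))
    as.matrix(newdata[object$linear_vars]) else matrix(0, n, 0)
  eta <- drop(cbind(1, Xl) %*% object$beta)
  for (j in seq_along(object$smooth_vars)) {
    v <- object$smooth_vars[j]
    eta <- eta + stats::predict(object$loess[[j]],
                                newdata = data.frame(xx = newdata[[v]])) -
      object$offsets[j]
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' Regularized feature selection (lasso and random-forest arms)
#'
#' Selection-validation pair run beside the stepwise additive model: a
#' coordinate-descent logistic lasso over a lambda path with the penalty
#' chosen by repeated cross-validated AUC, and a random forest whose
#' features are admitted by a permutation-importance gate (features whose
#' permutation-AUC drop is positive). Both arms report their selected set,
#' an importance ranking, and the out-of-fold AUC distribution.
#'
#' @param data complete numeric covariate data.frame.
#' @param y binary outcome.
#' @param repeats,folds repeated-CV scheme (default 5 x 10).
#' @param n_trees forest size for the RF arm.
#' @param seed integer seed.
#' @return list of class `regularized_selection` with elements `lasso` and
#'   `rf`, each holding `selected`, `importance` (named, decreasing), and
#'   `cv_auc` (out-of-fold AUCs); lasso also records `lambda`.
#' @export
regularized_selection <- function(data, y, repeats = 5, folds = 10,
                                  n_trees = 300, seed = 1L) {
  y <- as.integer(as.logical(y))
  X <- as.matrix(data)
  stopifnot(all(is.finite(X)))
  n <- nrow(X)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))

  ## ---- lasso arm ----
  full <- glmnet::glmnet(X, y, family = "binomial", standardize = TRUE)
  lam <- full$lambda
  auc_mat <- matrix(NA_real_, nrow = repeats * folds, ncol = length(lam))
  row <- 0
  cv_auc_lasso <- c()
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      test <- fold_id == f
      if (length(unique(y[test])) < 2 || length(unique(y[!test])) < 2)
        stop("regularized_selection: degenerate fold (single class)")
      fit <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test],
                            family = "binomial", standardize = TRUE,
                            lambda = lam)
      pr <- stats::predict(fit, X[test, , drop = FALSE], type = "response")
      row <- row + 1
      auc_mat[row, seq_len(ncol(pr))] <-
        apply(pr, 2, function(p) auc_rank(p, y[test]))
    }
  }
  mean_auc <- colMeans(auc_mat, na.rm = TRUE)
  best <- which.max(mean_auc)
  cv_auc_lasso <- auc_mat[, best]
  cf <- stats::coef(full, s = lam[best])[-1, 1]
  lasso_sel <- names(cf)[cf != 0]
  lasso_imp <- sort(abs(cf), decreasing = TRUE)

  ## ---- random-forest arm ----
  df <- data.frame(data, .y = factor(y))
  rf <- ranger::ranger(.y ~ ., data = df, num.trees = n_trees,
                       probability = TRUE, seed = child_seed(seed, 7))
  base_pred <- stats::predict(rf, data)$predictions[, "1"]
  base_auc <- auc_rank(base_pred, y)
  perm_imp <- vapply(names(data), function(v) {
    d2 <- data
    d2[[v]] <- d2[[v]][sample.int(n)]
    base_auc - auc_rank(stats::predict(rf, d2)$predictions[, "1"], y)
  }, numeric(1))
  rf_sel <- names(perm_imp)[perm_imp > 0]
  rf_imp <- sort(perm_imp, decreasing = TRUE)
  cv_auc_rf <- numeric(0)
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      test <- fold_id == f
      fit <- ranger::ranger(.y ~ ., data = df[!test, , drop = FALSE],
                            num.trees = n_trees, probability = TRUE,
                            seed = child_seed(seed, 100 + r * folds + f))
      pr <- stats::predict(fit, df[test, , drop = FALSE])$predictions[, "1"]
      cv_auc_rf <- c(cv_auc_rf, auc_rank(pr, y[test]))
    }
  }

  structure(list(
    lasso = list(selected = lasso_sel, importance = lasso_imp,
                 cv_auc = cv_auc_lasso, lambda = lam[best]),
    rf = list(selected = rf_sel, importance = rf_imp, cv_auc = cv_auc_rf)
  ), class = "regularized_selection")
}
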