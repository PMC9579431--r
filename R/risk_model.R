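#' Univariable spline-logistic screening of candidate AKI factors
#'
#' Fits, for each candidate, a univariable logistic model of the outcome:
#' numeric candidates enter through a restricted cubic spline basis (3 knots,
#' 2 df) and are tested by the likelihood-ratio test over all spline terms;
#' binary candidates enter linearly and are tested by the Wald z test.
#' Candidates with p below `alpha` are flagged for the multivariable model.
#'
#' Complete separation (fitted probabilities collapsing to 0/1) is detected
#' and the p-value replaced by one from a ridge-penalized refit, with the
#' candidate flagged in the `separation` column.
#'
#' @param data data.frame of candidate covariates (complete).
#' @param y binary outcome vector (both classes present).
#' @param alpha screening threshold (default 0.2).
#' @return data.frame of class `screen_result`: variable, type, p, keep,
#'   separation.
#' @export
univariable_screen <- function(data, y, alpha = 0.2) {
  y <- as.integer(as.logical(y))
  stopifnot(length(unique(y)) == 2, nrow(data) == length(y))
  rows <- lapply(names(data), function(nm) {
    x <- data[[nm]]
    binary <- length(unique(x)) <= 2
    if (binary) {
      fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
      sep <- detect_separation(fit)
      if (sep) {
        p <- ridge_logistic_lrt(cbind(x), y)
      } else {
        p <- summary(fit)$coefficients["x", "Pr(>|z|)"]
      }
      data.frame(variable = nm, type = "binary", p = p, separation = sep)
    } else {
      B <- rcs_basis(x)
      fit <- suppressWarnings(stats::glm(y ~ B, family = stats::binomial()))
      null <- stats::glm(y ~ 1, family = stats::binomial())
      sep <- detect_separation(fit)
      if (sep) {
        p <- ridge_logistic_lrt(B, y)
      } else {
        lrt <- null$deviance - fit$deviance
        p <- stats::pchisq(lrt, df = ncol(B), lower.tail = FALSE)
      }
      data.frame(variable = nm, type = "numeric", p = p, separation = sep)
    }
  })
  out <- do.call(rbind, rows)
  out$keep <- out$p < alpha
  class(out) <- c("screen_result", "data.frame")
  out
}

detect_separation <- function(fit) {
  probs <- stats::fitted(fit)
  eps <- 1e-8
  cf <- stats::coef(fit)[-1]
  !fit$converged || any(abs(cf) > 15, na.rm = TRUE) ||
    all(probs > 1 - eps | probs < eps)
}

# LRT under a small ridge penalty; a finite-estimate fallback for separated
# fits. Penalty excluded from the null so the statistic stays >= 0.
ridge_logistic_lrt <- function(X, y, lambda = 1e-2) {
  fit <- ridge_irls(X, y, lambda)
  null <- stats::glm(y ~ 1, family = stats::binomial())
  lrt <- max(null$deviance - fit$deviance, 0)
  stats::pchisq(lrt, df = ncol(X), lower.tail = FALSE)
}

# Penalized iteratively-reweighted least squares for logistic regression
# with an L2 penalty on non-intercept coefficients.
ridge_irls <- function(X, y, lambda = 0, max_iter = 100, tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X1 * w)
    beta_new <- solve(XtW %*% X1 + pen, XtW %*% z)
    beta <- drop(beta_new)
    mu <- stats::plogis(drop(X1 %*% beta))
    dev <- -2 * sum(y * log(pmax(mu, 1e-12)) +
                      (1 - y) * log(pmax(1 - mu, 1e-12)))
    if (abs(dev_old - dev) < tol) break
    dev_old <- dev
  }
  list(coefficients = beta, deviance = dev, fitted = mu, iterations = it)
}

#' Fit the multivariable additive logistic risk model
#'
#' Penalized-likelihood generalized additive model with a logistic link:
#' binary covariates enter linearly, numeric covariates through penalized
#' cubic regression smooths with one smoothing parameter each, selected by
#' GCV (REML available via `method`). Delegates the penalized IRLS fit to
#' mgcv and wraps it with the package's prediction/attribution contract.
#'
#' @param data data.frame holding all covariates (complete).
#' @param y binary outcome.
#' @param smooth_vars names of numeric covariates to smooth.
#' @param linear_vars names of covariates entering linearly.
#' @param k basis dimension per smooth (default 5; effective df are
#'   penalized below this).
#' @param method smoothing-parameter criterion, "GCV.Cp" or "REML".
#' @param sp optional fixed smoothing parameters (recycled over smooths);
#'   `sp = 0` gives the unpenalized spline fit.
#' @return object of class `aki_gam`: the mgcv fit plus term metadata.
#' @export
fit_additive_model <- function(data, y, smooth_vars = character(),
                               linear_vars = character(), k = 5,
                               method = "GCV.Cp", sp = NULL) {
  stopifnot(all(c(smooth_vars, linear_vars) %in% names(data)))
  y <- as.integer(as.logical(y))
  df <- data[, c(smooth_vars, linear_vars), drop = FALSE]
  df$.y <- y
  terms <- c(
    if (length(smooth_vars))
      paste0("s(", smooth_vars, ", bs = \"cr\", k = ", k, ")"),
    linear_vars
  )
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(".y ~", rhs))
  args <- list(formula = fml, data = df, family = stats::binomial(),
               method = method)
  if (!is.null(sp) && length(smooth_vars))
    args$sp <- rep_len(sp, length(smooth_vars))
  fit <- do.call(mgcv::gam, args)
  if (!fit$converged) stop("fit_additive_model: penalized IRLS did not converge")
  structure(list(fit = fit, smooth_vars = smooth_vars,
                 linear_vars = linear_vars, k = k, method = method),
            class = "aki_gam")
}

#' Predicted AKI probability from an additive risk model
#'
#' @param object an `aki_gam`.
#' @param newdata data.frame with the model's covariates.
#' @param type "response" (probability) or "link" (logit).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.aki_gam <- function(object, newdata, type = c("response", "link"),
                            ...) {
  type <- match.arg(type)
  as.numeric(mgcv::predict.gam(object$fit, newdata = newdata, type = type))
}

# Per-term approximate p-values: smooth terms from the s.table, linear terms
# from the Wald z test in the parametric table.
term_pvalues <- function(model) {
  sm <- summary(model$fit)
  p <- c()
  if (length(model$smooth_vars)) {
    st <- sm$s.table
    p_s <- st[, "p-value"]
    names(p_s) <- model$smooth_vars
    p <- c(p, p_s)
  }
  if (length(model$linear_vars)) {
    pt <- sm$p.table
    for (v in model$linear_vars) {
      row <- grep(paste0("^", v), rownames(pt), value = TRUE)[1]
      p_v <- pt[row, "Pr(>|z|)"]
      names(p_v) <- v
      p <- c(p, p_v)
    }
  }
  p
}

#' Supervised backward selection with forced covariates
#'
#' Starting from the screened term set, iteratively refits the additive
#' model and drops the non-forced term with the largest p-value at or above
#' `alpha`, until every non-forced term is significant. Forced covariates
#' (by convention the severity score, so the model stays adjusted for
#' severity) are retained regardless of their p-value.
#'
#' @inheritParams fit_additive_model
#' @param forced character vector of covariates never dropped.
#' @param alpha retention threshold (default 0.05).
#' @return list: `model` (final `aki_gam`), `trace` (data.frame of dropped
#'   terms with their p at removal), `selected` (retained covariate names).
#' @export
stepwise_select <- function(data, y, smooth_vars = character(),
                            linear_vars = character(),
                            forced = character(), alpha = 0.05, k = 5,
                            method = "GCV.Cp") {
  stopifnot(all(forced %in% c(smooth_vars, linear_vars)))
  if (length(c(smooth_vars, linear_vars)) == 0)
    stop("stepwise_select: empty candidate set")
  trace <- data.frame(variable = character(), p = numeric())
  repeat {
    model <- fit_additive_model(data, y, smooth_vars, linear_vars,
                                k = k, method = method)
    p <- term_pvalues(model)
    droppable <- setdiff(names(p), forced)
    if (length(droppable) == 0) break
    worst <- droppable[which.max(p[droppable])]
    if (p[worst] < alpha) break
    trace <- rbind(trace, data.frame(variable = worst, p = p[worst]))
    smooth_vars <- setdiff(smooth_vars, worst)
    linear_vars <- setdiff(linear_vars, worst)
  }
  list(model = model, trace = trace,
       selected = c(model$smooth_vars, model$linear_vars))
}

#' Discrimination and calibration of a fitted risk model
#'
#' AUC by the midrank Mann-Whitney formulation with a stratified-bootstrap
#' percentile CI; Hosmer-Lemeshow goodness-of-fit over 10 equal-count risk
#' groups (chi-squared with 8 df); and a calibration table of predicted vs
#' observed event rates per group.
#'
#' @param prob predicted probabilities (or a fitted `aki_gam` plus `data`).
#' @param y binary outcome.
#' @param n_boot bootstrap resamples for the AUC CI.
#' @param groups number of Hosmer-Lemeshow risk groups.
#' @param seed integer seed for the bootstrap.
#' @return list of class `model_evaluation`: auc, auc_ci, hl (statistic, df,
#'   p), calibration (data.frame).
#' @export
evaluate_model <- function(prob, y, n_boot = 2000, groups = 10, seed = 1L) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) stop("evaluate_model: single-class outcome")
  ci <- auc_boot_ci(prob, y, n_boot = n_boot, seed = seed)
  hl <- hosmer_lemeshow(prob, y, groups = groups)
  structure(list(auc = ci$auc, auc_ci = c(ci$lower, ci$upper),
                 hl = hl[c("statistic", "df", "p")],
                 calibration = hl$table),
            class = "model_evaluation")
}

#' Hosmer-Lemeshow calibration test
#'
#' Splits patients into `groups` equal-count bins of predicted risk and
#' compares observed and expected event counts:
#' \eqn{\sum_g (O_g - E_g)^2 / (E_g (1 - E_g/n_g))}, referred to a
#' chi-squared distribution with `groups - 2` df.
#'
#' @param prob predicted probabilities.
#' @param y binary outcome.
#' @param groups number of risk groups (default 10).
#' @return list: statistic, df, p, table (per-group n, observed, expected,
#'   mean predicted).
#' @export
hosmer_lemeshow <- function(prob, y, groups = 10) {
  y <- as.integer(as.logical(y))
  ord <- order(prob)
  bins <- cut(seq_along(ord), breaks = groups, labels = FALSE)
  g_idx <- split(ord[seq_along(ord)], bins)
  tab <- do.call(rbind, lapply(g_idx, function(ii) {
    data.frame(n = length(ii), observed = sum(y[ii]),
               expected = sum(prob[ii]), mean_pred = mean(prob[ii]),
               obs_rate = mean(y[ii]))
  }))
  denom <- tab$expected * (1 - tab$expected / tab$n)
  terms <- ifelse(denom > 0, (tab$observed - tab$expected)^2 / denom, 0)
  stat <- sum(terms)
  df <- groups - 2
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Partial dependence of predicted AKI risk on one covariate
#'
#' For each grid point g, the mean predicted probability over the cohort
#' with the covariate set to g and all other covariates at their observed
#' values. Outside the observed range the natural-spline basis extrapolates
#' linearly (a warning is issued).
#'
#' @param model an `aki_gam` or `aki_loess_gam`.
#' @param data covariate data.frame the averaging runs over.
#' @param var covariate name.
#' @param grid numeric grid (default: 50 points over the observed range).
#' @return data.frame: grid value, mean probability, mean logit.
#' @export
partial_dependence <- function(model, data, var, grid = NULL) {
  vars <- if (inherits(model, "aki_gam"))
    c(model$smooth_vars, model$linear_vars) else model$vars
  if (!var %in% vars) stop("partial_dependence: ", var, " not in model")
  x <- data[[var]]
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 50)
  if (any(grid < min(x) | grid > max(x)))
    warning("partial_dependence: grid extends beyond observed range; ",
            "natural-spline extrapolation is linear")
  res <- vapply(grid, function(g) {
    d <- data
    d[[var]] <- g
    mean(predict(model, d, type = "response"))
  }, numeric(1))
  logit <- vapply(grid, function(g) {
    d <- data
    d[[var]] <- g
    mean(predict(model, d, type = "link"))
  }, numeric(1))
  data.frame(grid = grid, prob = res, logit = logit)
}
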