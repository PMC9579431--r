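#' Yeo-Johnson power transform
#'
#' The Yeo-Johnson family extends the Box-Cox power transform to the whole
#' real line and is used here to symmetrize skewed clinical covariates
#' (lab values, severity scores) before model fitting.
#'
#' @param x numeric vector (finite).
#' @param lambda transform exponent.
#' @return transformed vector, same length as `x`.
#' @export
yeo_johnson <- function(x, lambda) {
  stopifnot(is.numeric(x), all(is.finite(x)), is.finite(lambda))
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-300 && any(pos))
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  if (abs(lambda) <= 1e-300 && any(pos))
    out[pos] <- log1p(x[pos])
  neg <- !pos
  if (abs(lambda - 2) > 1e-300 && any(neg))
    out[neg] <- -((1 - x[neg])^(2 - lambda) - 1) / (2 - lambda)
  if (abs(lambda - 2) <= 1e-300 && any(neg))
    out[neg] <- -log1p(-x[neg])
  out
}

# Profile log-likelihood of lambda under a Gaussian model on the transformed
# scale, including the Jacobian term (lambda - 1) * sum(sign(x) log(|x|+1)).
yj_loglik <- function(x, lambda) {
  z <- yeo_johnson(x, lambda)
  n <- length(x)
  s2 <- stats::var(z) * (n - 1) / n
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Maximum-likelihood Yeo-Johnson exponent
#'
#' Maximizes the profile log-likelihood over a bounded grid on
#' \[-3, 3\] (step 0.05) followed by golden-section refinement to 1e-4.
#'
#' @param x numeric vector with at least 10 finite values and nonzero variance.
#' @return the fitted lambda.
#' @export
fit_yeo_johnson <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("fit_yeo_johnson: need >= 10 finite values")
  if (stats::var(x) == 0) stop("fit_yeo_johnson: constant input")
  grid <- seq(-3, 3, by = 0.05)
  ll <- vapply(grid, function(l) yj_loglik(x, l), numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(l) yj_loglik(x, l),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-4)
  opt$maximum
}

#' Fit per-feature normalization parameters
#'
#' For every numeric (non-binary) column: fits the Yeo-Johnson exponent on
#' observed values, then records the mean and standard deviation of the
#' transformed values so new data can be mapped onto the same scale. Binary
#' 0/1 columns pass through untouched.
#'
#' @param data data.frame of covariates (may contain NA).
#' @param exclude character vector of column names to leave untouched.
#' @return an object of class `aki_transform` (list of per-feature
#'   lambda/center/scale).
#' @export
fit_normalization <- function(data, exclude = character()) {
  stopifnot(is.data.frame(data))
  params <- list()
  for (nm in names(data)) {
    x <- data[[nm]]
    if (!is.numeric(x) || nm %in% exclude) next
    obs <- x[is.finite(x)]
    if (length(unique(obs)) <= 2 && all(obs %in% c(0, 1))) next  # binary passthrough
    lambda <- fit_yeo_johnson(obs)
    z <- yeo_johnson(obs, lambda)
    s <- stats::sd(z)
    if (s <= 0) stop("fit_normalization: zero variance after transform in ", nm)
    params[[nm]] <- list(lambda = lambda, center = mean(z), scale = s)
  }
  structure(list(features = params), class = "aki_transform")
}

#' Apply fitted normalization to a data set
#'
#' @param object an `aki_transform` from [fit_normalization()].
#' @param data data.frame containing the fitted features.
#' @return data.frame with transformed, centered, scaled numeric columns;
#'   NA cells stay NA; untouched columns pass through.
#' @export
apply_normalization <- function(object, data) {
  stopifnot(inherits(object, "aki_transform"))
  for (nm in names(object$features)) {
    if (!nm %in% names(data)) stop("apply_normalization: missing column ", nm)
    p <- object$features[[nm]]
    x <- data[[nm]]
    ok <- is.finite(x)
    x[ok] <- (yeo_johnson(x[ok], p$lambda) - p$center) / p$scale
    data[[nm]] <- x
  }
  data
}

#' Serialize / restore normalization parameters as plain text
#'
#' Key-value text format (`feature<TAB>lambda<TAB>center<TAB>scale`) so a
#' fitted transform can be re-applied to new data outside R.
#'
#' @param object an `aki_transform`.
#' @param path file path.
#' @export
write_transform <- function(object, path) {
  stopifnot(inherits(object, "aki_transform"))
  df <- do.call(rbind, lapply(names(object$features), function(nm) {
    p <- object$features[[nm]]
    data.frame(feature = nm, lambda = p$lambda, center = p$center,
               scale = p$scale)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @return `read_transform` returns the restored `aki_transform`.
#' @export
read_transform <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  params <- lapply(seq_len(nrow(df)), function(i)
    list(lambda = df$lambda[i], center = df$center[i], scale = df$scale[i]))
  names(params) <- df$feature
  structure(list(features = params), class = "aki_transform")
}

#' Bagged-tree imputation of missing covariates
#'
#' For each feature with missing cells, fits an ensemble of `n_trees` CART
#' trees on bootstrap resamples of the rows observed for that feature
#' (predictors = all other features, with surrogate splits handling their
#' missingness) and fills each missing cell with the ensemble mean
#' (numeric) or majority vote (categorical).
#'
#' @param data data.frame; columns numeric or factor.
#' @param n_trees trees per feature ensemble.
#' @param seed integer seed.
#' @param min_leaf minimum observations per terminal leaf.
#' @return completed data.frame (observed cells unchanged).
#' @export
bagged_impute <- function(data, n_trees = 25, seed = 1L, min_leaf = 5) {
  stopifnot(is.data.frame(data), n_trees >= 1)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  out <- data
  targets <- names(data)[vapply(data, function(x) anyNA(x), logical(1))]
  for (nm in targets) {
    obs <- which(!is.na(data[[nm]]))
    mis <- which(is.na(data[[nm]]))
    if (length(obs) == 0) stop("bagged_impute: feature entirely missing: ", nm)
    train <- data[obs, , drop = FALSE]
    newx <- data[mis, setdiff(names(data), nm), drop = FALSE]
    fml <- stats::as.formula(paste0("`", nm, "` ~ ."))
    categorical <- is.factor(data[[nm]])
    preds <- matrix(NA_real_, nrow = length(mis), ncol = n_trees)
    votes <- if (categorical)
      matrix(NA_character_, nrow = length(mis), ncol = n_trees) else NULL
    for (b in seq_len(n_trees)) {
      bi <- sample.int(nrow(train), replace = TRUE)
      fit <- rpart::rpart(
        fml, data = train[bi, , drop = FALSE],
        method = if (categorical) "class" else "anova",
        control = rpart::rpart.control(minbucket = min_leaf, cp = 0,
                                       maxsurrogate = 5, xval = 0))
      if (categorical) {
        votes[, b] <- as.character(stats::predict(fit, newx, type = "class"))
      } else {
        preds[, b] <- stats::predict(fit, newx)
      }
    }
    if (categorical) {
      filled <- apply(votes, 1, function(v) names(which.max(table(v))))
      out[mis, nm] <- factor(filled, levels = levels(data[[nm]]))
    } else {
      out[mis, nm] <- rowMeans(preds)
    }
  }
  out
}

#' Iterative collinearity pruning
#'
#' While any pair of numeric features has absolute Pearson correlation above
#' `threshold`, removes from the worst offending pair the member with the
#' larger mean absolute correlation to all remaining features.
#'
#' @param data data.frame with >= 2 numeric columns (complete cases used).
#' @param threshold correlation cutoff (default 0.8).
#' @return list of class `collinearity_report`: `correlation` (the original
#'   matrix), `removed` (in removal order), `kept`, `threshold`.
#' @export
prune_collinear <- function(data, threshold = 0.8) {
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(num) < 2) stop("prune_collinear: need >= 2 numeric features")
  cmat <- stats::cor(data[num], use = "pairwise.complete.obs")
  work <- cmat
  removed <- character()
  repeat {
    a <- abs(work)
    diag(a) <- 0
    if (all(a <= threshold, na.rm = TRUE) || nrow(a) < 2) break
    worst <- which(a == max(a, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair <- rownames(a)[worst]
    mean_abs <- vapply(pair, function(f) mean(a[f, setdiff(rownames(a), f)]),
                       numeric(1))
    # drop the member more entangled with everything else; ties -> first name
    drop <- pair[which.max(mean_abs)]
    removed <- c(removed, drop)
    keep <- setdiff(rownames(work), drop)
    work <- work[keep, keep, drop = FALSE]
  }
  structure(list(correlation = cmat, removed = removed,
                 kept = rownames(work), threshold = threshold),
            class = "collinearity_report")
}

#' Inject missingness into a covariate table
#'
#' Masks numeric covariate cells completely at random (MCAR) or with
#' probability increasing in a fully observed driver covariate (MAR, logistic
#' in the driver's standardized value). Outcome labels and identifier
#' columns are never masked.
#'
#' @param data data.frame.
#' @param rate target masking proportion in \[0, 1).
#' @param mechanism "MCAR" or "MAR".
#' @param driver column name driving MAR missingness (required for MAR;
#'   never masked itself).
#' @param protect column names never masked (e.g. outcome, id).
#' @param seed integer seed.
#' @return data.frame with NAs injected.
#' @export
inject_missingness <- function(data, rate, mechanism = c("MCAR", "MAR"),
                               driver = NULL, protect = character(),
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(data)
  if (mechanism == "MAR") {
    if (is.null(driver) || !driver %in% names(data))
      stop("inject_missingness: MAR requires a named driver covariate")
    if (anyNA(data[[driver]]))
      stop("inject_missingness: MAR driver must be fully observed")
    protect <- union(protect, driver)
  }
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  maskable <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      protect)
  for (nm in maskable) {
    n <- nrow(data)
    p <- if (mechanism == "MCAR") {
      rep(rate, n)
    } else {
      z <- scale(data[[driver]])[, 1]
      pr <- stats::plogis(stats::qlogis(rate) + 1.5 * z)
      pr * rate / mean(pr)  # recalibrate so the marginal rate stays at `rate`
    }
    mask <- stats::runif(n) < pmin(p, 0.999)
    data[[nm]][mask] <- NA
  }
  data
}
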