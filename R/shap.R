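#' Configuration of the Shapley value function
#'
#' Controls how the conditional expectation v(S) = E\[f(X) | X_S = x_S\] is
#' estimated when attributing a patient's predicted AKI risk to the selected
#' features. `marginal` overwrites the coalition's columns in every
#' background row and averages the predictions (interventional
#' expectation). `empirical_conditional` does the same substitution but
#' weights background rows by a Gaussian kernel on the scaled Euclidean
#' distance, within the coalition's columns, between the background row and
#' the patient — an empirical estimate of the conditional expectation that
#' respects dependence between features.
#'
#' @param background data.frame of background rows (the reference
#'   population; by convention the full training cohort, so the base value
#'   is the cohort-level expected risk).
#' @param features character vector of attribution features (default: all
#'   background columns).
#' @param approach "marginal" (default; attributions of planted dominant
#'   factors stay crisp under correlated covariates, which the downstream
#'   clustering depends on) or "empirical_conditional".
#' @param sigma kernel bandwidth on standardized features (default 0.1).
#' @param max_background cap on background rows (subsampled
#'   deterministically by taking the first rows if exceeded).
#' @param output "probability" (default; row sums of the attribution matrix
#'   equal predicted AKI probability) or "link".
#' @return list of class `shap_config`.
#' @export
shap_config <- function(background, features = NULL,
                        approach = c("marginal", "empirical_conditional"),
                        sigma = 0.1, max_background = Inf,
                        output = c("probability", "link")) {
  approach <- match.arg(approach)
  output <- match.arg(output)
  stopifnot(is.data.frame(background), nrow(background) >= 1, sigma > 0)
  if (is.null(features)) features <- names(background)
  stopifnot(all(features %in% names(background)))
  if (nrow(background) > max_background)
    background <- background[seq_len(max_background), , drop = FALSE]
  scales <- vapply(features, function(f) {
    s <- stats::sd(background[[f]])
    if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1))
  structure(list(background = background, features = features,
                 approach = approach, sigma = sigma, output = output,
                 scales = scales),
            class = "shap_config")
}

# Evaluate a model on new data on the requested output scale. Models may be
# fitted `aki_gam`/`aki_loess_gam` objects or plain functions
# data.frame -> numeric (used by tests and toy models; functions are taken
# to already return the requested scale).
eval_model <- function(model, newdata, output = "probability") {
  if (is.function(model)) return(as.numeric(model(newdata)))
  type <- if (output == "probability") "response" else "link"
  predict(model, newdata, type = type)
}

# Additive term decomposition f(x) = intercept + sum_j t_j(x_j) on the link
# scale, when the model supports it (fast path for coalition enumeration).
# Returns NULL for models without one.
shap_terms <- function(model, data, features) {
  if (!inherits(model, "aki_gam")) return(NULL)
  tm <- mgcv::predict.gam(model$fit, newdata = data, type = "terms")
  cols <- colnames(tm)
  map <- vapply(features, function(f) {
    hit <- which(cols == f | cols == paste0("s(", f, ")"))
    if (length(hit) != 1) NA_integer_ else hit
  }, integer(1))
  if (anyNA(map)) return(NULL)
  list(intercept = attr(tm, "constant"), terms = tm[, map, drop = FALSE])
}

#' Value of a feature coalition
#'
#' Estimates v(S) = E\[f(X) | X_S = x_S\] for one patient and one coalition
#' under the configured value function. v(empty set) is the mean prediction
#' over the background; v(full set) equals f(x) for both approaches.
#'
#' @param model fitted risk model (or prediction function).
#' @param x one-row data.frame for the patient.
#' @param S character vector of features in the coalition (may be empty).
#' @param config a [shap_config()].
#' @return scalar coalition value.
#' @export
coalition_value <- function(model, x, S, config) {
  stopifnot(inherits(config, "shap_config"), all(S %in% config$features))
  mask <- as.integer(config$features %in% S)
  drop(coalition_values(model, x, matrix(mask, ncol = 1), config))
}

# All coalition values for one patient at once. `masks` is a p x K 0/1
# matrix (columns = coalitions). Returns length-K numeric.
coalition_values <- function(model, x, masks, config) {
  feats <- config$features
  bg <- config$background
  m <- nrow(bg)
  p <- length(feats)
  K <- ncol(masks)

  # kernel weights per coalition (empirical_conditional); marginal = uniform
  if (config$approach == "empirical_conditional") {
    D <- vapply(seq_len(p), function(j) {
      ((bg[[feats[j]]] - x[[feats[j]]][1]) / config$scales[j])^2
    }, numeric(m))
    if (m == 1) D <- matrix(D, nrow = 1)
    d2 <- D %*% masks                       # m x K squared distances
    W <- exp(-d2 / (2 * config$sigma^2))
    W <- sweep(W, 2, colSums(W), "/")
  } else {
    W <- matrix(1 / m, m, K)
  }

  tm <- tryCatch(shap_terms(model, rbind(x[feats], bg[feats]), feats),
                 error = function(e) NULL)
  if (!is.null(tm)) {
    # additive fast path: eta(mask, k) assembled from per-term contributions
    tx <- tm$terms[1, ]
    tb <- tm$terms[-1, , drop = FALSE]
    vals <- vapply(seq_len(K), function(ci) {
      s <- masks[, ci] == 1
      eta <- tm$intercept + sum(tx[s]) +
        (if (any(!s)) rowSums(tb[, !s, drop = FALSE]) else 0)
      out <- if (config$output == "probability") stats::plogis(eta) else eta
      sum(W[, ci] * out)
    }, numeric(1))
    return(vals)
  }

  # generic path: materialize every (coalition x background) hybrid row
  big <- bg[rep(seq_len(m), K), , drop = FALSE]
  for (j in seq_len(p)) {
    on <- which(masks[j, ] == 1)
    if (length(on)) {
      rows <- as.vector(outer(seq_len(m), (on - 1) * m, `+`))
      big[rows, feats[j]] <- x[[feats[j]]][1]
    }
  }
  pred <- eval_model(model, big, config$output)
  vals <- vapply(seq_len(K), function(ci) {
    sum(W[, ci] * pred[(ci - 1) * m + seq_len(m)])
  }, numeric(1))
  vals
}

#' Exact Shapley attribution for one patient
#'
#' Enumerates all 2^p coalitions of the p selected features (ascending
#' bitmask order, each value computed once) and combines them with the
#' Shapley kernel weights |S|! (p-|S|-1)! / p! to give each feature its
#' average marginal contribution to the patient's predicted AKI risk. The
#' base value is v(empty set), the expected prediction over the background;
#' by the efficiency axiom base value + sum of contributions equals the
#' patient's prediction exactly.
#'
#' @param model fitted risk model (or prediction function).
#' @param x one-row data.frame.
#' @param config a [shap_config()].
#' @return list: `phi` (named contribution vector), `base_value`,
#'   `prediction`.
#' @export
exact_shapley <- function(model, x, config) {
  feats <- config$features
  p <- length(feats)
  if (p > 15)
    stop("exact_shapley: more than 15 features; exact enumeration is 2^p — ",
         "use a sampling approximation instead")
  K <- 2^p
  masks <- vapply(0:(K - 1), function(b) as.integer(bitwAnd(b, 2^(0:(p - 1))) > 0),
                  integer(p))
  if (p == 1) masks <- matrix(masks, nrow = 1)
  v <- coalition_values(model, x, masks, config)
  sizes <- colSums(masks)
  lfac <- lfactorial(0:p)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    bit <- 2^(i - 1)
    without <- which(bitwAnd(0:(K - 1), bit) == 0L)
    s <- sizes[without]                      # |S| for S not containing i
    w <- exp(lfac[s + 1] + lfac[p - s] - lfac[p + 1])
    phi[i] <- sum(w * (v[without + bit] - v[without]))
  }
  names(phi) <- feats
  list(phi = phi, base_value = v[1], prediction = v[K])
}

#' Shapley attribution matrix for a cohort
#'
#' Runs [exact_shapley()] for every retained patient and assembles the
#' patients x features attribution matrix. Rows are restricted to patients
#' with the restricting label (AKI patients, by the pipeline's convention)
#' while the background population stays as configured.
#'
#' @param model fitted risk model.
#' @param data covariate data.frame for all patients.
#' @param config a [shap_config()].
#' @param restrict logical vector over rows of `data` (TRUE = keep), or
#'   NULL to keep all.
#' @return object of class `shap_matrix`: `phi` (matrix), `base_value`,
#'   `prediction`, `features`, `row_ids` (row indices into `data`).
#' @export
shap_matrix <- function(model, data, config, restrict = NULL) {
  if (is.null(restrict)) restrict <- rep(TRUE, nrow(data))
  stopifnot(length(restrict) == nrow(data))
  keep <- which(restrict)
  if (length(keep) == 0) stop("shap_matrix: no patients with the label")
  res <- lapply(keep, function(i)
    exact_shapley(model, data[i, , drop = FALSE], config))
  phi <- do.call(rbind, lapply(res, `[[`, "phi"))
  rownames(phi) <- keep
  structure(list(phi = phi,
                 base_value = res[[1]]$base_value,
                 prediction = vapply(res, `[[`, numeric(1), "prediction"),
                 features = config$features, row_ids = keep),
            class = "shap_matrix")
}

#' Global feature importance and plotting export of a Shapley matrix
#'
#' Global importance is the mean absolute contribution per feature; the
#' export lists (feature, phi, covariate value) triples per patient for
#' beeswarm-style displays.
#'
#' @param sm a `shap_matrix`.
#' @param data optional covariate data.frame to pull original values from.
#' @return list: `importance` (named, decreasing), `export` (long
#'   data.frame).
#' @export
shap_summary <- function(sm, data = NULL) {
  stopifnot(inherits(sm, "shap_matrix"), nrow(sm$phi) >= 1)
  imp <- sort(colMeans(abs(sm$phi)), decreasing = TRUE)
  export <- do.call(rbind, lapply(sm$features, function(f) {
    data.frame(feature = f,
               phi = sm$phi[, f],
               value = if (is.null(data)) NA_real_
                       else data[[f]][sm$row_ids],
               row_id = sm$row_ids)
  }))
  list(importance = imp, export = export)
}

#' Write / read a Shapley matrix as delimited text
#'
#' The matrix is written with a header row naming features plus a sidecar
#' metadata file recording the base value, approach, bandwidth and a hash
#' of the background.
#'
#' @param sm a `shap_matrix`.
#' @param path CSV path (sidecar written at `<path>.meta`).
#' @param config the `shap_config` used (for metadata).
#' @export
write_shap_matrix <- function(sm, path, config = NULL) {
  df <- data.frame(row_id = sm$row_ids, prediction = sm$prediction,
                   sm$phi, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(sprintf("base_value\t%.17g", sm$base_value),
            if (!is.null(config)) c(
              paste0("approach\t", config$approach),
              sprintf("sigma\t%g", config$sigma),
              sprintf("background_hash\t%d",
                      sum(as.integer(as.factor(format(unlist(config$background[config$features]), digits = 10)))))))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
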