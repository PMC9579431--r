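# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths.

# Shapley value by full permutation enumeration: mean marginal contribution
# over all p! orderings. v_fun maps a character vector of feature names to
# a coalition value.
permutation_shapley <- function(features, v_fun) {
  p <- length(features)
  perms <- all_permutations(seq_len(p))
  phi <- setNames(numeric(p), features)
  for (ord in perms) {
    prev <- character(0)
    for (i in ord) {
      f <- features[i]
      phi[f] <- phi[f] + v_fun(c(prev, f)) - v_fun(prev)
      prev <- c(prev, f)
    }
  }
  phi / length(perms)
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# Brute-force DBSCAN over the full distance matrix with union-find over
# core points; border points attach to the first core neighbor in index
# order (same convention as the package, different mechanics).
dbscan_reference <- function(X, eps, min_pts) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in which(core)) for (j in nb[[i]]) {
    if (core[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  labels <- integer(n)
  roots <- unique(vapply(which(core), find, integer(1)))
  for (i in which(core)) labels[i] <- match(find(i), roots)
  for (i in which(!core)) {
    cands <- nb[[i]][core[nb[[i]]]]
    if (length(cands)) labels[i] <- labels[cands[1]]
  }
  labels
}

# Agreement of two labelings up to renumbering (noise label 0 must match
# exactly).
same_partition <- function(a, b) {
  if (!all((a == 0) == (b == 0))) return(FALSE)
  keep <- a != 0
  if (!any(keep)) return(TRUE)
  tab <- table(a[keep], b[keep])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Mean silhouette width of a labeling from raw coordinates.
mean_silhouette <- function(X, labels) {
  d <- as.matrix(stats::dist(X))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Direct Hosmer-Lemeshow computation from a grouped table.
hl_direct <- function(prob, y, groups = 10) {
  ord <- order(prob)
  bins <- cut(seq_along(ord), breaks = groups, labels = FALSE)
  stat <- 0
  for (g in seq_len(groups)) {
    ii <- ord[bins == g]
    O <- sum(y[ii]); E <- sum(prob[ii]); n_g <- length(ii)
    stat <- stat + (O - E)^2 / (E * (1 - E / n_g))
  }
  stat
}

# Exhaustive metabolic rule table (written independently from the package
# rule, directly from the five published profile definitions plus the
# gap-closure convention).
metabolic_rule_oracle <- function(lac, glu, med, q25, q75) {
  if (lac >= med) {
    if (glu >= q75) "stress_response" else "impaired_metabolism"
  } else {
    if (glu >= q75) "isolated_hyperglycaemia"
    else if (glu < q25) "isolated_hypoglycaemia"
    else "baseline"
  }
}

# Convenience: logistic prediction function on a linear score, for toy
# SHAP models (a plain function is a valid model for the attribution API).
linear_prob_model <- function(beta0, beta) {
  function(newdata) {
    eta <- beta0 + as.matrix(newdata[names(beta)]) %*% beta
    stats::plogis(drop(eta))
  }
}
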