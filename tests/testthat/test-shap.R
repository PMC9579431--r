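make_bg <- function(n, p, seed = 1) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * p), n))
  names(d) <- paste0("f", seq_len(p))
  d
}

test_that("coalition values hit their closed-form anchors", {
  bg <- make_bg(5, 3)
  model <- linear_prob_model(0.2, c(f1 = 1, f2 = -0.5, f3 = 0.8))
  x <- bg[3, ]
  for (approach in c("marginal", "empirical_conditional")) {
    cfg <- shap_config(bg, approach = approach)
    expect_equal(coalition_value(model, x, character(0), cfg),
                 mean(model(bg)))
    expect_equal(coalition_value(model, x, names(bg), cfg),
                 as.numeric(model(x)), tolerance = 1e-12)
  }
  # marginal v(S) equals the hand-enumerated mean of overwritten predictions
  cfg <- shap_config(bg, approach = "marginal")
  S <- c("f1", "f3")
  hybrid <- bg
  hybrid$f1 <- x$f1
  hybrid$f3 <- x$f3
  expect_equal(coalition_value(model, x, S, cfg), mean(model(hybrid)),
               tolerance = 1e-12)
})

test_that("exact Shapley equals the linear closed form with marginal values", {
  bg <- make_bg(40, 4, seed = 2)
  beta <- c(f1 = 0.7, f2 = -1.1, f3 = 0.4, f4 = 0)
  lin_model <- function(newdata)             # identity output scale
    0.3 + drop(as.matrix(newdata[names(beta)]) %*% beta)
  cfg <- shap_config(bg, approach = "marginal")
  x <- bg[7, ]
  res <- exact_shapley(lin_model, x, cfg)
  closed <- beta * unlist(x[names(beta)] - colMeans(bg[names(beta)]))
  expect_equal(res$phi, closed, tolerance = 1e-8)
  # dummy axiom: a feature the model ignores gets exactly zero
  expect_lt(abs(res$phi["f4"]), 1e-12)
})

test_that("symmetric duplicated features receive equal attribution", {
  bg <- make_bg(30, 2, seed = 3)
  bg$f2 <- bg$f1                                  # duplicated in background
  model <- function(newdata) plogis(0.5 * newdata$f1 + 0.5 * newdata$f2)
  cfg <- shap_config(bg, approach = "marginal")
  x <- data.frame(f1 = 1.3, f2 = 1.3)             # duplicated in the instance
  res <- exact_shapley(model, x, cfg)
  expect_equal(res$phi[["f1"]], res$phi[["f2"]], tolerance = 1e-10)
})

test_that("enumeration equals the permutation-form oracle up to p = 5", {
  for (p in 2:5) {
    bg <- make_bg(12, p, seed = 10 + p)
    beta <- setNames(seq_len(p) / p, names(bg))
    model <- linear_prob_model(-0.2, beta)
    cfg <- shap_config(bg, approach = "marginal")
    x <- bg[5, ]
    res <- exact_shapley(model, x, cfg)
    v_fun <- function(S) coalition_value(model, x, S, cfg)
    oracle <- permutation_shapley(names(bg), v_fun)
    expect_equal(res$phi, oracle[names(res$phi)], tolerance = 1e-10)
    # efficiency as telescoping identity
    expect_equal(res$base_value + sum(res$phi), res$prediction,
                 tolerance = 1e-10)
  }
})

test_that("efficiency holds for every patient under both value functions", {
  bg <- make_bg(60, 4, seed = 20)
  model <- linear_prob_model(0.1, c(f1 = 1, f2 = 0.6, f3 = -0.9, f4 = 0.3))
  for (approach in c("marginal", "empirical_conditional")) {
    cfg <- shap_config(bg, approach = approach)
    sm <- shap_matrix(model, bg, cfg)
    deficit <- sm$base_value + rowSums(sm$phi) - sm$prediction
    tol <- if (approach == "marginal") 1e-10 else 1e-8
    expect_lt(max(abs(deficit)), tol)
  }
})

test_that("attribution matrix restriction and per-patient independence", {
  bg <- make_bg(50, 3, seed = 30)
  model <- linear_prob_model(0, c(f1 = 1, f2 = 1, f3 = 1))
  cfg <- shap_config(bg)
  lab <- rep(c(TRUE, FALSE), length.out = 50)
  sm <- shap_matrix(model, bg, cfg, restrict = lab)
  expect_equal(nrow(sm$phi), sum(lab))
  expect_equal(sm$row_ids, which(lab))
  expect_error(shap_matrix(model, bg, cfg, restrict = rep(FALSE, 50)),
               "no patients")

  # permuting patient order permutes rows identically
  perm <- sample(50)
  sm2 <- shap_matrix(model, bg[perm, ], cfg, restrict = lab[perm])
  m1 <- sm$phi[order(perm[sm2$row_ids])[rank(sm$row_ids)], , drop = FALSE]
  expect_equal(unname(sm2$phi[order(sm2$row_ids), ]),
               unname(sm2$phi[order(sm2$row_ids), ]))
  # direct check: each permuted row equals the original row of that patient
  orig_ids <- perm[sm2$row_ids]
  reord <- match(orig_ids, sm$row_ids)
  expect_equal(unname(sm2$phi), unname(sm$phi[reord, ]), tolerance = 1e-12)
})

test_that("summary importance is the mean absolute attribution", {
  phi <- rbind(c(0.2, 0, -0.4), c(-0.1, 0, 0.6), c(0.3, 0, 0.1))
  colnames(phi) <- c("a", "b", "c")
  sm <- structure(list(phi = phi, base_value = 0.4,
                       prediction = rep(0.5, 3), features = colnames(phi),
                       row_ids = 1:3), class = "shap_matrix")
  s <- shap_summary(sm)
  expect_equal(unname(s$importance),
               unname(sort(colMeans(abs(phi)), decreasing = TRUE)),
               tolerance = 1e-12)
  expect_equal(names(s$importance)[3], "b")    # all-zero column ranks last
  # scaling a column up cannot lower its rank
  phi2 <- phi; phi2[, "a"] <- phi2[, "a"] * 10
  sm2 <- sm; sm2$phi <- phi2
  s2 <- shap_summary(sm2)
  expect_lte(match("a", names(s2$importance)), match("a", names(s$importance)))
})

test_that("enumeration scales to the pipeline's own size within budget", {
  bg <- make_bg(120, 7, seed = 40)
  beta <- setNames(rep(0.4, 7), names(bg))
  model <- linear_prob_model(-0.3, beta)
  cfg <- shap_config(bg)
  t0 <- Sys.time()
  sm <- shap_matrix(model, bg[1:20, ], cfg)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 60)
  expect_equal(dim(sm$phi), c(20L, 7L))
  expect_error(
    exact_shapley(model, bg[1, ],
                  shap_config(make_bg(5, 16), approach = "marginal")),
    "15")
})
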