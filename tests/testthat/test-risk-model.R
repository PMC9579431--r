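test_that("univariable screen reports calibrated LRT p-values and flags separation", {
  # LRT statistic equals the deviance difference from the package-independent
  # penalized-IRLS oracle run unpenalized, on a fixed 12-row dataset
  set.seed(41)
  x <- c(0.1, 0.5, 0.9, 1.3, 1.8, 2.2, 2.9, 3.3, 3.8, 4.4, 4.9, 5.5)
  y <- c(0, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 1)
  scr <- univariable_screen(data.frame(v = x), y)
  B <- rcs_basis(x)
  oracle <- akiphen:::ridge_irls(B, y, lambda = 0)
  null_dev <- -2 * sum(y * log(mean(y)) + (1 - y) * log(1 - mean(y)))
  lrt <- null_dev - oracle$deviance
  expect_equal(scr$p, pchisq(lrt, 2, lower.tail = FALSE), tolerance = 1e-6)

  # a binary candidate equal to the outcome is flagged as separated
  scr2 <- univariable_screen(data.frame(v = y), y)
  expect_true(scr2$separation)
  expect_true(is.finite(scr2$p))
})

test_that("screen type-I error rate is near the nominal alpha", {
  set.seed(42)
  n <- 2000
  rej <- vapply(1:120, function(i) {
    y <- rbinom(n, 1, 0.4)
    x <- rnorm(n)
    univariable_screen(data.frame(v = x), y, alpha = 0.2)$keep
  }, logical(1))
  expect_gt(mean(rej), 0.12)
  expect_lt(mean(rej), 0.28)
})

test_that("additive model shrinks a linear effect toward 1 effective df", {
  set.seed(43)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  fit <- fit_additive_model(data.frame(x = x), y, smooth_vars = "x")
  edf <- summary(fit$fit)$s.table[1, "edf"]
  expect_gte(edf, 0.9)
  expect_lte(edf, 1.6)
})

test_that("unpenalized additive fit matches the IRLS oracle in the sp -> 0 limit", {
  set.seed(44)
  n <- 150
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  fit <- fit_additive_model(data.frame(x = x), y, smooth_vars = "x",
                            k = 4, sp = 0)
  # oracle: logistic fit on the same mgcv basis, via independent IRLS
  X <- stats::model.matrix(fit$fit)[, -1, drop = FALSE]
  oracle <- akiphen:::ridge_irls(X, y, lambda = 0)
  expect_equal(fit$fit$deviance, oracle$deviance, tolerance = 1e-6)
})

test_that("intercept-only model predicts the prevalence", {
  set.seed(45)
  y <- rbinom(300, 1, 0.35)
  fit <- fit_additive_model(data.frame(z = rnorm(300)), y)
  p <- predict(fit, data.frame(z = rnorm(10)))
  expect_equal(p, rep(mean(y), 10), tolerance = 1e-8)
})

test_that("backward selection keeps forced terms and significant terms", {
  set.seed(46)
  n <- 800
  d <- data.frame(s1 = rnorm(n), s2 = rnorm(n), noise = rnorm(n),
                  forced_null = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.3 + 1.2 * d$s1 + 0.9 * d$s2))
  sel <- stepwise_select(d, y, smooth_vars = c("s1", "s2", "noise"),
                         linear_vars = "forced_null",
                         forced = "forced_null")
  expect_true(all(c("s1", "s2", "forced_null") %in% sel$selected))
  expect_false("noise" %in% sel$selected)

  # already-significant model is left unchanged
  sel2 <- stepwise_select(d, y, smooth_vars = c("s1", "s2"), forced = character())
  expect_setequal(sel2$selected, c("s1", "s2"))
  expect_equal(nrow(sel2$trace), 0)
  expect_error(stepwise_select(d, y), "empty")
})

test_that("forced terms survive selection across random specifications", {
  set.seed(47)
  for (r in 1:15) {
    n <- 300
    d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- rbinom(n, 1, plogis(0.8 * d$a))
    forced <- sample(c("b", "c"), 1)
    sel <- stepwise_select(d, y, smooth_vars = c("a", "b", "c"),
                           forced = forced, alpha = 0.05)
    expect_true(forced %in% sel$selected)
  }
})

test_that("model evaluation: perfect ranking, null behavior and HL oracle", {
  y <- rep(c(0, 1), each = 25)
  ev <- evaluate_model(y, y, n_boot = 100, seed = 1)   # predictions = labels
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$hl$statistic, 0, tolerance = 1e-10)

  set.seed(48)
  y2 <- rbinom(5000, 1, 0.4)
  p2 <- runif(5000)
  ev2 <- evaluate_model(p2, y2, n_boot = 100, seed = 2)
  expect_gt(ev2$auc, 0.47)
  expect_lt(ev2$auc, 0.53)

  # 20-row fixture with hand-assigned probabilities against the direct formula
  set.seed(49)
  p3 <- round(runif(20, 0.05, 0.95), 2)
  y3 <- rbinom(20, 1, p3)
  if (length(unique(y3)) == 1) y3[1] <- 1 - y3[1]
  hl <- hosmer_lemeshow(p3, y3, groups = 5)
  expect_equal(hl$statistic, hl_direct(p3, y3, groups = 5), tolerance = 1e-10)
  expect_equal(hl$df, 3)
})

test_that("partial dependence is affine for linear terms and additive for smooths", {
  set.seed(50)
  n <- 500
  d <- data.frame(x = rnorm(n), w = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(0.9 * d$x - 0.4 * d$w))
  fit <- fit_additive_model(d, y, linear_vars = c("x", "w"))
  grid <- seq(-2, 2, length.out = 25)
  pd <- partial_dependence(fit, d, "x", grid)
  # logit of the PD of a purely linear model is affine in the grid
  co <- coef(lm(pd$logit ~ grid))
  expect_lt(max(abs(pd$logit - (co[1] + co[2] * grid))), 1e-8)
  expect_true(all(diff(pd$prob) > 0))

  # additive model: PD logit differs from the fitted smooth by a constant
  d2 <- data.frame(x = rnorm(n), z = rnorm(n))
  y2 <- rbinom(n, 1, plogis(0.8 * d2$x + sin(d2$z)))
  fit2 <- fit_additive_model(d2, y2, smooth_vars = c("x", "z"))
  g2 <- seq(-1.5, 1.5, length.out = 15)
  pd2 <- partial_dependence(fit2, d2, "z", g2)
  nd <- data.frame(x = 0, z = g2)
  tm <- mgcv::predict.gam(fit2$fit, nd, type = "terms")
  smooth_part <- tm[, "s(z)"]
  dev <- pd2$logit - smooth_part
  expect_lt(max(dev) - min(dev), 1e-8)
})

test_that("partial dependence recovers a planted u-shape", {
  set.seed(51)
  n <- 3000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.8 + 0.9 * (x^2 - 1)))
  fit <- fit_additive_model(data.frame(x = x), y, smooth_vars = "x")
  grid <- seq(-2, 2, length.out = 30)
  pd <- partial_dependence(fit, data.frame(x = x), "x", grid)
  slopes <- sign(diff(pd$logit))
  changes <- sum(diff(slopes) != 0)
  expect_equal(changes, 1)             # one sign change: down then up
  expect_lt(slopes[1], 0)
  expect_gt(slopes[length(slopes)], 0)
})
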