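test_that("cohort thresholds use linear-interpolation quantiles", {
  thr <- compute_metabolic_thresholds(c(1, 2, 3), 1:8)
  expect_equal(thr$lactate_median, 2)
  expect_equal(thr$glucose_q25, 2.75)
  expect_equal(thr$glucose_q50, 4.5)
  expect_equal(thr$glucose_q75, 6.25)

  same <- compute_metabolic_thresholds(c(1, 2), rep(5.5, 10))
  expect_equal(same$glucose_q25, same$glucose_q75)
  expect_error(compute_metabolic_thresholds(1, 1:8), "insufficient")
})

test_that("five-state classification matches the rule table", {
  thr <- structure(list(lactate_median = 1.5, glucose_q25 = 5,
                        glucose_q50 = 7, glucose_q75 = 10),
                   class = "metabolic_thresholds")
  expect_equal(classify_metabolic_state(2.0, 12, thr), "stress_response")
  expect_equal(classify_metabolic_state(2.0, 8, thr), "impaired_metabolism")
  expect_equal(classify_metabolic_state(1.0, 12, thr), "isolated_hyperglycaemia")
  expect_equal(classify_metabolic_state(1.0, 3, thr), "isolated_hypoglycaemia")
  expect_equal(classify_metabolic_state(1.0, 6, thr), "baseline")
  # boundary convention: "above" = >=
  expect_equal(classify_metabolic_state(1.5, 10, thr), "stress_response")
  expect_equal(classify_metabolic_state(1.4999, 5, thr), "baseline")
  # gap closure: lactate below median, glucose in [q50, q75) -> baseline
  expect_equal(classify_metabolic_state(1.0, 8, thr), "baseline")
})

test_that("classification agrees with the independent rule oracle", {
  thr <- structure(list(lactate_median = 1.6, glucose_q25 = 4.8,
                        glucose_q50 = 7.1, glucose_q75 = 9.9),
                   class = "metabolic_thresholds")
  set.seed(91)
  lac <- runif(2000, 0.2, 5)
  glu <- runif(2000, 1, 20)
  got <- classify_metabolic_state(lac, glu, thr)
  want <- mapply(metabolic_rule_oracle, lac, glu,
                 MoreArgs = list(med = 1.6, q25 = 4.8, q75 = 9.9))
  expect_identical(got, unname(want))
})

test_that("occupancy times integrate the step function exactly", {
  thr <- structure(list(lactate_median = 1.5, glucose_q25 = 5,
                        glucose_q50 = 7, glucose_q75 = 10),
                   class = "metabolic_thresholds")
  # single measurement: full stay in its profile
  s1 <- metabolic_summary(2, 2.0, 12, thr, icu_admission = 0,
                          icu_discharge = 10)
  expect_equal(s1$relative_time[["stress_response"]], 1)
  expect_equal(s1$dominant, "stress_response")

  # two measurements, switch at the exact midpoint
  s2 <- metabolic_summary(c(0, 5), c(2.0, 1.0), c(12, 6), thr, 0, 10)
  expect_equal(s2$relative_time[["stress_response"]], 0.5)
  expect_equal(s2$relative_time[["baseline"]], 0.5)

  # irregular 5-measurement fixture against hand-integrated occupancy:
  # profiles: stress (0 to 2), impaired (2 to 3.5), baseline (3.5 to 7),
  # stress (7 to 8.25), hypo (8.25 to 10)
  s3 <- metabolic_summary(
    time = c(1, 2, 3.5, 7, 8.25),
    lactate = c(2.0, 2.0, 1.0, 2.0, 1.0),
    glucose = c(12, 8, 6, 12, 3),
    thr, icu_admission = 0, icu_discharge = 10)
  expect_equal(s3$relative_time[["stress_response"]], (2 + 1.25) / 10,
               tolerance = 1e-12)
  expect_equal(s3$relative_time[["impaired_metabolism"]], 1.5 / 10,
               tolerance = 1e-12)
  expect_equal(s3$relative_time[["baseline"]], 3.5 / 10, tolerance = 1e-12)
  expect_equal(s3$relative_time[["isolated_hypoglycaemia"]], 1.75 / 10,
               tolerance = 1e-12)
  expect_equal(s3$dominant, "baseline")
  expect_error(metabolic_summary(numeric(0), numeric(0), numeric(0), thr, 0, 1))
})

test_that("relative occupancy sums to one on random series", {
  thr <- structure(list(lactate_median = 1.5, glucose_q25 = 5,
                        glucose_q50 = 7, glucose_q75 = 10),
                   class = "metabolic_thresholds")
  set.seed(92)
  for (r in 1:200) {
    k <- sample(1:12, 1)
    tt <- sort(runif(k, 0, 9.5))
    tt <- tt[!duplicated(round(tt, 6))]
    s <- metabolic_summary(tt, rlnorm(length(tt), 0.3, 0.4),
                           rlnorm(length(tt), 2, 0.3), thr, 0, 10)
    expect_equal(sum(s$relative_time), 1, tolerance = 1e-9)
  }
})
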