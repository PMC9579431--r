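traj <- function(time, creat, ...) creatinine_trajectory(1, time, creat, ...)

test_that("AKI detection follows the ratio and absolute criteria", {
  # constant trajectory: no AKI
  t0 <- traj(0:10, rep(80, 11))
  expect_false(detect_aki(t0)$aki)

  # ratio rule: 130/80 = 1.625 >= 1.5 at day 3
  t1 <- traj(c(0, 1, 2, 3), c(80, 82, 85, 130))
  d1 <- detect_aki(t1)
  expect_true(d1$aki)
  expect_equal(d1$onset, 3)
  expect_equal(d1$criterion, "ratio")

  # absolute rule: 110 >= 80 + 26.4 although 110/80 = 1.375 < 1.5
  t2 <- traj(c(0, 1), c(80, 110))
  d2 <- detect_aki(t2)
  expect_true(d2$aki)
  expect_equal(d2$criterion, "absolute")
  expect_equal(d2$onset, 1)

  # absolute criterion is windowed at 48 h: a slow creep of +30 over 5 days
  # with no 48-h jump >= 26.4 and ratio < 1.5 stays AKI-free
  t3 <- traj(0:5, c(80, 86, 92, 98, 104, 110))
  expect_false(detect_aki(t3)$aki)

  # ratio rule is windowed at 7 days: the reference minimum rolls forward
  t4 <- traj(c(0, 8, 9), c(60, 100, 151))
  d4 <- detect_aki(t4)
  expect_true(d4$aki)               # 151/100.. vs min over (2,9] = 100 -> 1.51
  expect_equal(d4$onset, 9)
})

test_that("KDIGO staging maps peak ratios and RRT to the documented stages", {
  s1 <- stage_kdigo(traj(c(0, 2, 4), c(80, 100, 176)))      # ratio 2.2
  expect_equal(s1$stage, "2")
  s2 <- stage_kdigo(traj(c(0, 2, 4), c(80, 150, 280)))      # ratio 3.5
  expect_equal(s2$stage, "3-noRRT")
  s3 <- stage_kdigo(traj(c(0, 2), c(80, 128), rrt = TRUE, rrt_start = 2))
  expect_equal(s3$stage, "3-RRT")                           # RRT dominates
  s4 <- stage_kdigo(traj(c(0, 2), c(80, 128)))              # ratio 1.6
  expect_equal(s4$stage, "1")
  # absolute-criterion-only episode is stage 1
  s5 <- stage_kdigo(traj(c(0, 1), c(100, 130)))             # +30, ratio 1.3
  expect_equal(s5$stage, "1")
  # peak above 353.6 umol/L forces stage 3 regardless of ratio
  s6 <- stage_kdigo(traj(c(0, 1), c(200, 360)))             # ratio 1.8
  expect_equal(s6$stage, "3-noRRT")
  # RRT without creatinine AKI warns and stages 3-RRT
  expect_warning(
    s7 <- stage_kdigo(traj(0:3, c(80, 81, 80, 82), rrt = TRUE, rrt_start = 1)),
    "RRT")
  expect_equal(s7$stage, "3-RRT")
})

test_that("recovery needs creatinine below 1.5x baseline and no ongoing RRT", {
  tr <- traj(c(0, 2, 4, 6), c(80, 160, 130, 85))
  rec <- assess_recovery(tr, stage_kdigo(tr))
  # 130 >= 1.5*80 = 120 -> not yet; 85 < 120 -> recovered at day 6
  expect_true(rec$recovered)
  expect_equal(rec$abs_time, 6)

  plateau <- traj(c(0, 2, 4, 6, 8), c(80, 176, 150, 130, 128))
  rec2 <- assess_recovery(plateau, stage_kdigo(plateau))
  expect_false(rec2$recovered)      # plateaus at 1.6x baseline

  # below threshold but still on RRT: recovery waits for RRT to stop
  rrt_tr <- traj(c(0, 2, 4, 6), c(80, 176, 110, 108),
                 rrt = TRUE, rrt_start = 2, rrt_end = 5)
  rec3 <- assess_recovery(rrt_tr, stage_kdigo(rrt_tr))
  expect_true(rec3$recovered)
  expect_equal(rec3$abs_time, 6)    # day 4 blocked by ongoing RRT

  rrt_on <- traj(c(0, 2, 4), c(80, 176, 110),
                 rrt = TRUE, rrt_start = 2, rrt_end = NA)
  rec4 <- assess_recovery(rrt_on, stage_kdigo(rrt_on))
  expect_false(rec4$recovered)
})

test_that("staging is monotone under upward scaling of the episode", {
  stage_rank <- c("0" = 0, "1" = 1, "2" = 2, "3-noRRT" = 3, "3-RRT" = 4)
  set.seed(81)
  for (r in 1:25) {
    base <- runif(1, 50, 120)
    peak_mult <- runif(1, 1.0, 3.2)
    tt <- seq(0, 10, by = 0.5)
    shape <- exp(-((tt - 5)^2) / 4)          # unimodal bump
    cc <- base * (1 + (peak_mult - 1) * shape)
    t_lo <- creatinine_trajectory(1, tt, cc)
    scale_up <- runif(1, 1, 1.5)
    cc_hi <- base * (1 + (peak_mult * scale_up - 1) * shape)
    t_hi <- creatinine_trajectory(1, tt, cc_hi)
    expect_gte(stage_rank[stage_kdigo(t_hi)$stage],
               stage_rank[stage_kdigo(t_lo)$stage])
  }
})

test_that("trajectory validation rejects malformed series", {
  expect_error(creatinine_trajectory(1, c(0, 1, 1), c(80, 81, 82)),
               "increasing")
  expect_error(creatinine_trajectory(1, 0:2, c(80, -1, 82)), "> 0")
})
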