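test_that("resilience and pressure combinations match hand evaluation", {
  expect_equal(combine_resilience(100, 100, 100), 100)
  expect_equal(combine_resilience(50, 50, 50, gamma = 0.2), 50)
  expect_equal(combine_resilience(80, 60, 40), 55)  # 0.5*(80+60)/2 + 0.5*40
  expect_equal(combine_pressure(0, 0), 0)
  expect_equal(combine_pressure(100, 100), 100)
  expect_equal(combine_pressure(30, 10), 20)
  expect_error(combine_resilience(120, 50, 50), "\\[0, 100\\]")
  expect_error(combine_pressure(-1, 50), "\\[0, 100\\]")
})

test_that("likely future status reproduces published projections and clamps", {
  # wild-capture fisheries row: exact at printed precision
  expect_equal(round(likely_future_status(54.00, 0.02, 16.69, 72.81), 2), 64.72)
  # mariculture row: raw projection 103.54 clamps to 100
  raw <- (1 + 0.67 * 0.04 + 0.33 * (68.68 - 14.01) / 100) * 85.77
  expect_equal(round(raw, 2), 103.54)
  expect_equal(likely_future_status(85.77, 0.04, 14.01, 68.68), 100)
  # neutral projection: zero trend, resilience equals pressure
  expect_equal(likely_future_status(47.3, 0, 55, 55), 47.3)
})

test_that("future status is always clamped to [0, 100] over random inputs", {
  set.seed(42)
  for (i in 1:200) {
    f <- likely_future_status(runif(1, 0, 100), runif(1, -1, 1),
                              runif(1, 0, 100), runif(1, 0, 100))
    expect_true(f >= 0 && f <= 100)
  }
})

test_that("goal score is the mean of status and future", {
  expect_equal(goal_score(58.66, 69.90), 64.28)
  expect_equal(goal_score(0, 0), 0)
  expect_equal(goal_score(100, 100), 100)
})

test_that("subgoal aggregation reproduces published goal rows", {
  # Biodiversity from its subgoal scores (printed as 91.05)
  expect_close(aggregate_subgoals(c(92.72, 89.39)), 91.055, 1e-12)
  # Food Provision status under the yield weights solved from the table
  w <- cohi_fp_yield_weights()
  expect_close(aggregate_subgoals(c(54.00, 85.77), w), 58.66, 1e-6)
  expect_close(aggregate_subgoals(c(59.36, 92.88), w), 64.28, 0.005)
  expect_equal(aggregate_subgoals(77.7, 2), 77.7)  # single subgoal
  expect_error(aggregate_subgoals(c(1, 2), c(0, 0)), "not all be zero")
})

test_that("index aggregation is scale invariant and matches the mean oracle", {
  scores <- c(a = 80, b = 60, c = 40.5, d = 99)
  w <- c(a = 0.1, b = 0.4, c = 0.2, d = 0.3)
  expect_equal(aggregate_index(scores, w), aggregate_index(scores, 7.3 * w))
  # equal weights, x_max = 100: index equals the plain mean
  set.seed(7)
  for (i in 1:20) {
    s <- setNames(runif(10, 0, 100), letters[1:10])
    expect_equal(aggregate_index(s), mean(s))
  }
  # single positive weight picks out that goal
  expect_equal(aggregate_index(scores, c(a = 0, b = 2, c = 0, d = 0)), 60)
  expect_error(aggregate_index(scores, c(a = 1, e = 1)), "missing an assessment")
})

test_that("index is strictly monotone in any positively weighted goal", {
  set.seed(11)
  s <- setNames(runif(10, 10, 90), letters[1:10])
  w <- setNames(runif(10, 0.1, 2), letters[1:10])
  base <- aggregate_index(s, w)
  for (g in names(s)) {
    bumped <- s
    bumped[g] <- bumped[g] + 1
    expect_gt(aggregate_index(bumped, w), base)
  }
})

test_that("recent trend matches the least-squares oracle", {
  # closed form: slope 0.02/yr on the 0-1 scale over 5 years
  expect_equal(recent_trend(2009:2013, c(50, 52, 54, 56, 58)), 0.10)
  expect_equal(recent_trend(2000:2010, rep(63, 11)), 0)
  expect_equal(recent_trend(2009:2013, c(100, 80, 55, 30, 2)), -1)  # clamped
  # random series against stats::lm
  set.seed(3)
  for (i in 1:10) {
    y <- runif(8, 0, 100)
    yr <- 2001:2008
    ols <- unname(coef(lm(I(y[4:8] / 100) ~ yr[4:8]))[2])
    expect_close(recent_trend(yr, y), clamp_manual(ols * 5), 1e-10)
  }
  expect_error(recent_trend(2010:2012, c(1, 2, 3)), "at least 5")
})

test_that("relative trend divides by the window mean", {
  y <- c(50, 52, 54, 56, 58)
  # slope 0.02/yr on the 0-1 scale, mean status 0.54, times the 5-yr window
  expect_close(recent_trend(2009:2013, y, type = "relative"),
               0.02 / 0.54 * 5, 1e-10)
})

test_that("CIW:GDP social score behaves as a baseline-anchored ratio", {
  yrs <- 1994:2013
  ciw <- seq(100, 119, 1)
  gdp <- seq(100, 138, 2)
  expect_equal(ciw_gdp_index(yrs, ciw, yrs, gdp, eval_year = 1994), 100)
  # CIW unchanged, GDP doubled
  expect_equal(ciw_gdp_index(c(1994, 2013), c(50, 50),
                             c(1994, 2013), c(80, 160), 2013), 50)
  # joint +10% cancels
  expect_equal(ciw_gdp_index(c(1994, 2013), c(50, 55),
                             c(1994, 2013), c(80, 88), 2013), 100)
  expect_error(ciw_gdp_index(yrs, ciw, yrs, gdp, eval_year = 1960), "lacks year")
  expect_error(ciw_gdp_index(c(1994, 2013), c(50, -1),
                             c(1994, 2013), c(80, 90), 2013), "positive")
  s <- social_layers_from_ciw(73)
  expect_equal(s$social_resilience + s$social_pressure, 100)
})

test_that("the engine reproduces the packaged national assessment", {
  ref <- cohi_goal_assessment()
  res <- cohi_assess(cohi_assessment_inputs(),
                     subgoal_weights = cohi_subgoal_weights())
  key_ref <- paste(ref$goal_id, ref$subgoal_id)
  key_res <- paste(res$goal_id, res$subgoal_id)
  m <- match(key_res, key_ref)
  expect_false(anyNA(m))
  # every published future and score within the rounding band of the inputs
  expect_true(all(abs(res$future - ref$future[m]) <= 0.15))
  expect_true(all(abs(res$score - ref$score[m]) <= 0.15))
  # rows where printed precision suffices are exact at 2 decimals
  fis <- res$future[res$subgoal_id %in% "FIS"]
  expect_equal(round(fis, 2), 64.72)
  clamped <- c("MAR", "ECO", "HAB")
  expect_equal(res$future[res$subgoal_id %in% clamped], rep(100, 3))
  expect_equal(res$future[res$goal_id == "CP" & is.na(res$subgoal_id)], 100)
  expect_close(attr(res, "index"), 64.55, 0.15)
  expect_close(attr(res, "future_index"), 67.65, 0.15)
})

test_that("goal-level rows in the input are recomputed, not trusted", {
  a <- cohi_assessment_inputs()
  a$status[a$goal_id == "BD" & is.na(a$subgoal_id)] <- 1  # poison
  res <- cohi_assess(a, subgoal_weights = cohi_subgoal_weights())
  bd <- res[res$goal_id == "BD" & is.na(res$subgoal_id), ]
  expect_close(bd$status, 84.825, 1e-9)
})
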