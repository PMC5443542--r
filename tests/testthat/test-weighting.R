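test_that("weight normalization shifts then scales, in that order", {
  expect_equal(normalize_weights(c(a = 0, b = 1)), c(a = 2 / 3, b = 4 / 3))
  expect_equal(normalize_weights(c(a = 4, b = 4, c = 4)),
               c(a = 1, b = 1, c = 1))
  # the post-scale minimum is generally below 1 (steps do not commute)
  w <- normalize_weights(c(a = -2, b = 0, c = 5))
  expect_lt(min(w), 1)
  expect_equal(sum(w), 3)
  expect_error(normalize_weights(c(1, 2)), "named")
  expect_error(normalize_weights(c(a = Inf)), "finite")
})

test_that("normalization sum invariant holds over random raw vectors", {
  set.seed(47)
  for (i in 1:500) {
    n <- sample(2:12, 1)
    raw <- setNames(rnorm(n, sd = 10^runif(1, -2, 2)), paste0("g", 1:n))
    expect_close(sum(normalize_weights(raw)), n, 1e-9)
  }
})

test_that("equal and Likert schemes behave as defined", {
  expect_equal(equal_weights(paste0("g", 1:10)),
               setNames(rep(1, 10), paste0("g", 1:10)))
  expect_error(equal_weights(character(0)), "at least one")
  # constant ratings collapse to equal weights
  lik <- expand.grid(respondent_id = paste0("r", 1:4), goal = c("A", "B", "C"),
                     stringsAsFactors = FALSE)
  lik$rating <- 5L
  expect_equal(likert_weights(lik), c(A = 1, B = 1, C = 1))
  # two goals with means 2 and 4: shift to (1, 3), scale to (0.5, 1.5)
  lik2 <- data.frame(respondent_id = c("r1", "r1", "r2", "r2"),
                     goal = c("A", "B", "A", "B"), rating = c(2L, 4L, 2L, 4L))
  expect_equal(likert_weights(lik2), c(A = 0.5, B = 1.5))
  expect_error(likert_weights(lik2, goals = c("A", "B", "C")), "no ratings")
})

test_that("best-worst rank weights use inverse ranks of net counts", {
  # goal A always best, C always worst -> net (n, 0, -n) -> raw (3, 2, 1)
  tasks <- data.frame(respondent_id = "r1", task_id = 1:4, shown = "A|B|C",
                      best = "A", worst = "C")
  w <- bw_rank_weights(tasks)
  expect_equal(w, normalize_weights(c(A = 3, B = 2, C = 1)))
  expect_equal(which.max(w), c(A = 1L))
  # identical counts: tie broken by goal order, message emitted
  tie <- data.frame(respondent_id = "r1", task_id = 1:2, shown = "A|B|C",
                    best = c("A", "B"), worst = c("B", "A"))
  expect_message(bw_rank_weights(tie), "ties")
})

test_that("maxdiff likelihood agrees with an independent implementation", {
  tasks <- tiny_tasks()
  fit <- fit_maxdiff_logit(tasks)
  goals <- c("A", "B", "C")
  expect_equal(sum(fit$utilities), 0, tolerance = 1e-10)
  # the reported maximum beats every point on a coarse grid of the
  # independently coded likelihood
  grid <- expand.grid(u1 = seq(-3, 3, 0.25), u2 = seq(-3, 3, 0.25))
  lls <- apply(grid, 1, function(p) {
    brute_maxdiff_ll(c(p[1], p[2], -p[1] - p[2]), tasks, goals)
  })
  expect_gte(fit$loglik, max(lls))
  # and matches the brute-force likelihood at the fitted point
  expect_close(brute_maxdiff_ll(fit$utilities, tasks, goals), fit$loglik, 1e-8)
  # brute-force optimum (Nelder-Mead on the independent likelihood)
  opt <- optim(c(0, 0), function(p) {
    -brute_maxdiff_ll(c(p[1], p[2], -p[1] - p[2]), tasks, goals)
  })
  expect_close(fit$loglik, -opt$value, 1e-4)
  expect_true(all(abs(fit$utilities[1:2] - opt$par) < 0.01))
})

test_that("uniform random choices give near-zero utilities", {
  set.seed(53)
  n <- 150
  goals <- paste0("g", 1:5)
  tasks <- do.call(rbind, lapply(1:n, function(i) {
    shown <- sample(goals, 4)
    bw <- sample(shown, 2)
    data.frame(respondent_id = sprintf("r%03d", i), task_id = 1,
               shown = paste(shown, collapse = "|"),
               best = bw[1], worst = bw[2], stringsAsFactors = FALSE)
  }))
  fit <- fit_maxdiff_logit(tasks)
  expect_true(all(abs(fit$utilities) < 3 * fit$se))
})

test_that("maxdiff recovery is unbiased and shift-invariant", {
  cfg <- generator_config(seed = 59, n_respondents = 200)
  survey <- gen_survey(cfg)
  fit <- fit_maxdiff_logit(survey$tasks, goals = cfg$goals)
  truth <- cfg$true_utilities - mean(cfg$true_utilities)
  expect_true(all(abs(fit$utilities - truth) < 3 * fit$se))
  # shifting all true utilities by a constant changes nothing observable
  shifted <- generator_config(seed = 59, n_respondents = 200,
                              true_utilities = cfg$true_utilities + 5)
  survey2 <- gen_survey(shifted)
  expect_identical(survey$tasks, survey2$tasks)
  # bias shrinks with sample size
  big <- gen_survey(generator_config(seed = 59, n_respondents = 2000))
  fit_big <- fit_maxdiff_logit(big$tasks, goals = cfg$goals)
  expect_lt(mean(abs(fit_big$utilities - truth)),
            mean(abs(fit$utilities - truth)))
})

test_that("DCE weights and spreads behave as designed", {
  expect_equal(dce_weights(c(a = 0, b = 0, c = 0)), c(a = 1, b = 1, c = 1))
  u <- c(a = 3, b = 0, c = -1)
  expect_equal(which.max(dce_weights(u)), c(a = 1L))
  # heterogeneous population: DCE spread at least the Likert spread
  cfg <- generator_config(seed = 61, n_respondents = 300)
  survey <- gen_survey(cfg)
  w_dce <- dce_weights(fit_maxdiff_logit(survey$tasks, goals = cfg$goals))
  w_lik <- likert_weights(survey$likert, goals = cfg$goals)
  expect_gte(diff(range(w_dce)), diff(range(w_lik)))
})

test_that("subgoal weight table applies the 0.5 rule and yield shares", {
  tab <- subgoal_weight_table(list(BD = c("HAB", "SPP"),
                                   FP = c("FIS", "MAR")),
                              fp_yield = c(FIS = 85, MAR = 15))
  expect_equal(tab$weight[tab$goal_id == "BD"], c(0.5, 0.5))
  expect_equal(tab$weight[tab$goal_id == "FP"], c(0.85, 0.15))
  expect_error(subgoal_weight_table(list(FP = c("FIS", "MAR"))), "yield")
  expect_error(subgoal_weight_table(list(FP = c("FIS", "MAR")),
                                    fp_yield = c(FIS = 0, MAR = 0)), "invalid")
})

test_that("group comparison separates planted preferences and not clones", {
  scored <- cohi_assess(cohi_assessment_inputs(),
                        subgoal_weights = cohi_subgoal_weights())
  top <- scored[is.na(scored$subgoal_id), ]
  goal_scores <- setNames(top$score, top$goal_id)
  goals <- names(goal_scores)
  # segment "hi" loves the high-scoring goals, "lo" the low-scoring ones
  ranks <- rank(goal_scores)
  u_hi <- setNames(2 * (ranks - mean(ranks)) / max(ranks), goals)
  u_lo <- -u_hi
  cfg <- generator_config(seed = 67, n_respondents = 60, n_tasks = 4)
  survey <- gen_survey(cfg, segments = list(hi = u_hi, lo = u_lo))
  res <- compare_groups(survey$tasks, survey$demographics, "segment",
                        goal_scores, n_sims = 150, seed = 101)
  expect_equal(nrow(res$groups), 2)
  expect_false(res$similar["hi", "lo"])
  expect_true(nchar(res$groups$letter[1]) > 0)
  expect_false(any(grepl(res$groups$letter[1], res$groups$letter[2],
                         fixed = TRUE)))
  # identical preference processes share a letter
  survey_same <- gen_survey(cfg, segments = list(x = u_hi, y = u_hi))
  res_same <- compare_groups(survey_same$tasks, survey_same$demographics,
                             "segment", goal_scores, n_sims = 100, seed = 102)
  expect_true(res_same$similar["x", "y"])
  expect_equal(res_same$groups$letter[1], res_same$groups$letter[2])
  expect_error(compare_groups(survey$tasks, survey$demographics, "segment",
                              goal_scores, n_sims = 0), "n_sims")
})

test_that("group comparison is deterministic given its seed", {
  scored <- cohi_assess(cohi_assessment_inputs(),
                        subgoal_weights = cohi_subgoal_weights())
  top <- scored[is.na(scored$subgoal_id), ]
  goal_scores <- setNames(top$score, top$goal_id)
  cfg <- generator_config(seed = 71, n_respondents = 20, n_tasks = 4)
  survey <- gen_survey(cfg)
  survey$demographics$half <- rep(c("A", "B"), 10)
  r1 <- compare_groups(survey$tasks, survey$demographics, "half",
                       goal_scores, n_sims = 25, seed = 5)
  r2 <- compare_groups(survey$tasks, survey$demographics, "half",
                       goal_scores, n_sims = 25, seed = 5)
  expect_identical(r1$sims, r2$sims)
  expect_identical(r1$groups, r2$groups)
})
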