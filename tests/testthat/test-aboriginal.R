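test_that("RNFB imputation evaluates the published linear predictors", {
  inuit <- cohi_rnfb_coefficients("Inuit")
  fn <- cohi_rnfb_coefficients("FirstNations")
  zero <- data.frame(group = "Inuit", population = 0, RNFB = 0, RNFB_dist = 0,
                     ICCPI = 0, ICCPI_dist = 0)
  expect_equal(impute_rnfb(zero, inuit), 1262)  # the intercept
  fn_row <- data.frame(group = "FirstNations", population = 0,
                       ICCPI = 100, ICCPI_dist = 0)
  expect_equal(impute_rnfb(fn_row, fn), 1606 - 12.86 * 100)
  # full Inuit predictor against independent scalar arithmetic
  row <- data.frame(group = "Inuit", population = 1000, RNFB = 400,
                    RNFB_dist = 100, ICCPI = 130, ICCPI_dist = 500)
  by_hand <- 1262 + 0.625 * 400 + 0.035 * 100 + (-10.89) * 130 +
    0.024 * 500 + (-0.007) * 1000
  expect_close(impute_rnfb(row, inuit), by_hand, 1e-9)
  expect_error(impute_rnfb(zero, fn), "group")
})

test_that("OLS refit recovers generating coefficients on noiseless data", {
  set.seed(31)
  truth <- cohi_rnfb_coefficients("Inuit")
  n <- 40
  d <- data.frame(group = "Inuit",
                  population = runif(n, 100, 3000),
                  RNFB = runif(n, 300, 500), RNFB_dist = runif(n, 0, 800),
                  ICCPI = runif(n, 90, 140), ICCPI_dist = runif(n, 0, 2000))
  d$price <- impute_rnfb(d, truth)
  fit <- suppressWarnings(fit_rnfb_model(d, "Inuit"))  # perfect-fit warning
  expect_true(all(abs(fit - truth[names(fit)]) < 1e-8))
  # fitted values reproduce the training predictions (projection property)
  refit_pred <- impute_rnfb(d, fit)
  expect_true(all(abs(refit_pred - d$price) < 1e-8))
})

test_that("OLS degenerate cases error and pure noise has near-zero R2", {
  set.seed(37)
  n <- 200
  d <- data.frame(group = "FirstNations",
                  population = runif(n, 100, 3000),
                  ICCPI = runif(n, 90, 140), ICCPI_dist = runif(n, 0, 2000),
                  price = rnorm(n, 1000, 100))
  fit <- fit_rnfb_model(d, "FirstNations")
  expect_lt(abs(attr(fit, "adj_r_squared")), 0.05)
  expect_error(fit_rnfb_model(d[1:4, ], "FirstNations"), "observations")
  collinear <- d
  collinear$ICCPI_dist <- 2 * collinear$ICCPI
  expect_error(fit_rnfb_model(collinear, "FirstNations"), "rank deficient")
})

test_that("ice cover fraction matches brute-force enumeration", {
  lat <- seq(60, 70, 0.5); lon <- seq(-75, -60, 0.5)
  ones <- grid_field(lat, lon, matrix(1, length(lat), length(lon)))
  zeros <- grid_field(lat, lon, matrix(0, length(lat), length(lon)))
  expect_equal(ice_cover_fraction(ones, 65, -68), 1)
  expect_equal(ice_cover_fraction(zeros, 65, -68), 0)
  # half-covered field: area-weighted brute force over qualifying cells
  vals <- outer(lat, lon, function(la, lo) as.numeric(lo > -68))
  half <- grid_field(lat, lon, vals)
  centre <- c(65, -68)
  num <- 0; den <- 0
  for (i in seq_along(lat)) {
    for (j in seq_along(lon)) {
      d <- haversine_km(lat[i], lon[j], centre[1], centre[2])
      if (d <= 300) {
        a <- 6371.0088^2 * (0.5 * pi / 180)^2 * cos(lat[i] * pi / 180)
        num <- num + a * vals[i, j]
        den <- den + a
      }
    }
  }
  expect_close(ice_cover_fraction(half, centre[1], centre[2]), num / den, 1e-9)
  expect_error(ice_cover_fraction(ones, 0, 100), "no grid cells")
})

test_that("the access factor reproduces the price-ratio cross-check", {
  expect_equal(community_an_factor(1, 1, 1, 1, 1, 1), 1)
  # food x3.0, fuel x5.5, unchanged ice: the published ~54-point scenario
  expect_close(100 * community_an_factor(3, 5.5, 1, 1, 1, 1), 54.55, 0.01)
  # an all-zero ice series contributes a ratio of exactly 1
  expect_equal(community_an_factor(2, 2, 0, 1, 1, 0, ice_all_zero = TRUE), 1)
  expect_equal(community_an_factor(2, 2, 0.5, 1, 1, 0), 1)  # Ib = 0 guard
  expect_error(community_an_factor(-1, 1, 1, 1, 1, 1), "positive")
})

test_that("the AN index is a population-weighted factor mean", {
  panel <- list(
    communities = data.frame(community_id = c("a", "b"),
                             population = c(100, 300)),
    series = data.frame(
      community_id = rep(c("a", "b"), each = 2),
      year = rep(c(1979, 2013), 2),
      food_price = c(100, 100, 100, 300),
      gas_price = c(10, 10, 10, 60),
      ice_fraction = c(0.8, 0.8, 0.9, 0.9)))
  expect_equal(an_index(panel, 1979)$score, 100)
  # factors: a = 1, b = (300/60)/(100/10) = 0.5 -> 0.25*1 + 0.75*0.5
  expect_equal(an_index(panel, 2013)$score, 62.5)
  # equal factors are population-invariant
  panel$series$food_price <- 100; panel$series$gas_price <- 10
  panel$series$ice_fraction <- rep(c(0.8, 0.4, 0.9, 0.45), 1)
  expect_close(an_index(panel, 2013)$score, 50, 1e-9)
  panel$communities$population <- c(999, 1)
  expect_close(an_index(panel, 2013)$score, 50, 1e-9)
})

test_that("AN is invariant to merging identical communities and monotone in gas", {
  cfg <- generator_config(seed = 41, n_communities = 6, price_noise_sd = 0)
  panel <- gen_communities(cfg)
  y <- max(cfg$years)
  base <- an_index(panel, y)
  # merge two communities with identical factors: same index
  merged <- panel
  s1 <- merged$series$community_id == "c001"
  s2 <- merged$series$community_id == "c002"
  merged$series[s2, -1] <- merged$series[s1, -1]
  merged2 <- merged
  merged2$communities <- merged2$communities[-2, ]
  merged2$communities$population[1] <-
    sum(merged$communities$population[1:2])
  merged2$series <- merged2$series[!s2, ]
  expect_close(an_index(merged2, y)$score, an_index(merged, y)$score, 1e-9)
  # raising one community's gas price strictly lowers the index
  dearer <- panel
  pick <- dearer$series$community_id == "c003" & dearer$series$year == y
  dearer$series$gas_price[pick] <- dearer$series$gas_price[pick] * 2
  expect_lt(an_index(dearer, y)$score, base$score)
})

test_that("a flat-then-declining world yields a flat-then-declining AN", {
  cfg <- generator_config(seed = 43, n_communities = 5,
                          gas_growth = 1, food_growth = 1,
                          ice_decline_start = 1999, ice_decline_total = 0.3,
                          price_noise_sd = 0)
  panel <- gen_communities(cfg)
  res <- an_series(panel)
  early <- res$series$score[res$series$year < 1999]
  late <- res$series$score[res$series$year >= 1999]
  expect_true(all(abs(early - 100) < 1e-9))
  expect_true(all(diff(late) < 0))
  expect_lt(res$trend, 0)
  expect_error(an_trend(2010:2012, c(1, 2, 3)), "at least 5")
})
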